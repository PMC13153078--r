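make_table <- function(n = 100, p = 4, seed = 1, beta = NULL, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- beta %||% rnorm(p)
  feature_table(X, target = as.numeric(X %*% beta + rnorm(n, 0, noise)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the 4:1 split is exact, disjoint, exhaustive and seeded", {
  ds <- simulate_dataset(seed = 1)
  ft <- build_feature_table(ds$spectra, ds$samples$lpn,
                            sample_ids = ds$samples$sample_id,
                            include_indices = FALSE)
  parts <- split_dataset(ft, split_spec(seed = 42))
  expect_equal(nrow(parts$train$values), 120)
  expect_equal(nrow(parts$test$values), 30)
  expect_length(intersect(parts$train_idx, parts$test_idx), 0)
  expect_setequal(c(parts$train_idx, parts$test_idx), seq_len(150))

  parts2 <- split_dataset(ft, split_spec(seed = 42))
  expect_identical(parts$train_idx, parts2$train_idx)
  parts3 <- split_dataset(ft, split_spec(seed = 43))
  expect_false(identical(parts$train_idx, parts3$train_idx))

  expect_error(split_spec(train_fraction = 1), class = "invalid_params")
  expect_error(split_dataset(subset_features(ft, samples = 1:3)),
               class = "contract_error")
})

test_that("stratified splitting respects the strata", {
  ds <- simulate_dataset(seed = 2)
  ft <- build_feature_table(ds$spectra, ds$samples$lpn,
                            sample_ids = ds$samples$sample_id,
                            include_indices = FALSE)
  parts <- split_dataset(ft, split_spec(seed = 1,
                                        stratify_by = ds$samples$treatment))
  tr_treat <- ds$samples$treatment[parts$train_idx]
  # 25 samples per treatment, 80% -> 20 in training from each
  expect_true(all(table(tr_treat) == 20))
})

test_that("MLR recovers an exact linear law and flags rank deficiency", {
  set.seed(11)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 2 * X[, 1] - X[, 2] + 3
  m <- fit_model(feature_table(X, target = y), "MLR")
  expect_equal(predict(m, X), y, tolerance = 1e-8)
  expect_equal(unname(m$fit$coefficients), c(2, -1), tolerance = 1e-8)
  expect_equal(unname(m$fit$intercept), 3, tolerance = 1e-8)

  Xd <- cbind(X, dup = X[, 1])
  err <- tryCatch(fit_model(feature_table(Xd, target = y), "MLR"),
                  error = function(e) e)
  expect_s3_class(err, "rank_deficiency")
  expect_match(conditionMessage(err), "dup")
})

test_that("NIPALS PLSR with full components reproduces least squares", {
  ft <- make_table(n = 150, p = 6, seed = 12)
  new <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  m_mlr <- fit_model(ft, "MLR")
  m_pls <- fit_model(ft, "PLSR", hyperparams = list(n_components = 6))
  expect_equal(predict(m_pls, new), predict(m_mlr, new), tolerance = 1e-6)

  # fewer components: still finite and sensible on signal-bearing data
  m3 <- fit_model(ft, "PLSR")
  expect_equal(m3$fit$n_components, 3)
  expect_true(all(is.finite(predict(m3, new))))
})

test_that("KNN honours k = 1 identity, convexity and statelessness", {
  set.seed(13)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rnorm(30)
  ft <- feature_table(X, target = y)

  m1 <- fit_model(ft, "KNN", hyperparams = list(k = 1))
  expect_equal(predict(m1, X[7, , drop = FALSE]), y[7])

  m5 <- fit_model(ft, "KNN")
  new <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  pred <- predict(m5, new)
  expect_true(all(pred >= min(y) & pred <= max(y)))
  # batch equals row-by-row
  expect_equal(pred, vapply(seq_len(20), function(i)
    predict(m5, new[i, , drop = FALSE]), numeric(1)))

  # distance ties broken by training-row order: three equidistant neighbours,
  # k = 2 must take the first two in storage order
  Xt <- matrix(c(1, -1, 1, 0, 0, 0), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  # standardization preserves the tie structure (symmetric +/- values)
  mt <- fit_model(feature_table(Xt, target = c(10, 20, 30)),
                  "KNN", hyperparams = list(k = 2))
  q <- matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(mt, q), mean(c(10, 20)))

  expect_error(fit_model(ft, "KNN", hyperparams = list(k = 31)),
               class = "invalid_params")
})

test_that("SVM regression fits, predicts finitely and deterministically", {
  ft <- make_table(n = 120, p = 4, seed = 14)
  m <- fit_model(ft, "SVM", seed = 5)
  new <- matrix(rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("f", 1:4)))
  p1 <- predict(m, new)
  expect_true(all(is.finite(p1)))
  m2 <- fit_model(ft, "SVM", seed = 5)
  expect_equal(predict(m2, new), p1)
  # strong linear signal: SVM predictions track the least-squares fit
  expect_gt(evaluate(p1, predict(fit_model(ft, "MLR"), new))$r2, 0.8)
})

test_that("evaluation reproduces the R2 and RMSE definitions", {
  obs <- c(1, 2, 3, 4, 5)
  e1 <- evaluate(obs, obs)
  expect_equal(e1$r2, 1)
  expect_equal(e1$rmse, 0)
  expect_equal(e1$n_test, 5)

  e2 <- evaluate(rep(mean(obs), 5), obs)
  expect_equal(e2$r2, 0)

  e3 <- evaluate(obs + 0.1, obs)
  expect_equal(e3$rmse, 0.1)

  expect_error(evaluate(obs, rep(2, 5)), class = "undefined_r2")
  expect_error(evaluate(1:3, 1:4), class = "contract_error")
})

test_that("local averaging beats saturated collinear regression under noise", {
  # deliberately pathological baseline: a saturated fit on 119 collinear raw
  # bands (intercept + 119 = 120 training rows) under realistic radiometric
  # noise memorizes the training set and collapses out of sample, while KNN on
  # the screened variables stays stable
  ds <- simulate_dataset(sensor = sensor_model(noise_sd = 0.15), seed = 9)
  ft <- build_feature_table(ds$spectra, ds$samples$lpn,
                            sample_ids = ds$samples$sample_id)
  parts <- split_dataset(ft, split_spec(seed = 10))
  bands <- grep("^B_", colnames(ft$values), value = TRUE)[
    unique(round(seq(1, 224, length.out = 119)))]
  tr_b <- subset_features(parts$train, bands)
  te_b <- subset_features(parts$test, bands)
  r2_mlr <- evaluate(predict(fit_model(tr_b, "MLR"), te_b), te_b$target)$r2

  sel <- resolve_variable_set(reference_variable_set(), ft)
  tr_s <- subset_features(parts$train, sel)
  te_s <- subset_features(parts$test, sel)
  r2_knn <- evaluate(predict(fit_model(tr_s, "KNN"), te_s), te_s$target)$r2

  expect_gt(r2_knn, r2_mlr)
})
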