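test_that("pearson_r reproduces its closed-form values and guards inputs", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "undefined_correlation")
  expect_error(pearson_r(1:3, 1:4), class = "contract_error")
})

test_that("gradient-boosted importances are a normalized distribution that finds signal", {
  set.seed(21)
  n <- 200
  y <- rnorm(n)
  X <- cbind(signal = y, matrix(rnorm(n * 10), n, 10,
                                dimnames = list(NULL, paste0("noise", 1:10))))
  ft <- feature_table(X, target = y)

  fi <- fi_scores(ft, seed = 1)
  expect_true(all(fi >= 0))
  expect_equal(sum(fi), 1, tolerance = 1e-9)
  # the feature equal to the target dominates
  expect_equal(names(which.max(fi)), "signal")
  expect_gt(fi["signal"], 0.9)

  # deterministic under a fixed seed
  expect_identical(fi, fi_scores(ft, seed = 1))

  ft_const <- feature_table(X, target = rep(1, n))
  expect_warning(fi0 <- fi_scores(ft_const, seed = 1), "constant target")
  expect_true(all(fi0 == 0))

  expect_error(fi_scores(feature_table(X[1:5, ], target = y[1:5])),
               class = "contract_error")
})

test_that("collinear pair pruning keeps the stronger target correlate", {
  # f1 tracks the target tightly, f2 is f1 plus noise: r(f1,f2) high,
  # |r_target| clearly larger for f1 -> f2 must be dropped
  set.seed(31)
  n <- 120
  y <- rnorm(n)
  f1 <- y + rnorm(n, 0, 0.3)
  f2 <- f1 + rnorm(n, 0, 0.45)
  ft <- feature_table(cbind(f1 = f1, f2 = f2), target = y)
  stopifnot(abs(cor(f1, f2)) >= 0.8,
            abs(cor(f1, y)) - abs(cor(f2, y)) >= 0.05)

  fi <- c(f1 = 0.5, f2 = 0.5)
  res <- select_variables(ft, selection_config(), fi = fi)
  expect_equal(res$selected, "f1")
  expect_equal(res$pruning_log$dropped, "f2")
  expect_match(res$pruning_log$rule, "weaker target correlation")
})

test_that("comparable target correlations fall back to importance, then name", {
  # near-duplicate features: target correlations within eps of each other
  set.seed(32)
  n <- 150
  y <- rnorm(n)
  f1 <- y + rnorm(n, 0, 0.2)
  f2 <- f1 + rnorm(n, 0, 0.02)
  ft <- feature_table(cbind(f1 = f1, f2 = f2), target = y)
  stopifnot(abs(abs(cor(f1, y)) - abs(cor(f2, y))) < 0.05)

  res <- select_variables(ft, selection_config(), fi = c(f1 = 0.1, f2 = 0.3))
  expect_equal(res$selected, "f2")  # higher importance retained
  expect_match(res$pruning_log$rule, "lower importance dropped")

  # identical importances: alphabetically first retained, rule logged
  ft2 <- feature_table(cbind(b = f1, a = f1), target = y)
  res2 <- select_variables(ft2, selection_config(), fi = c(b = 0.2, a = 0.2))
  expect_equal(res2$selected, "a")
  expect_match(res2$pruning_log$rule, "alphabetically")
})

test_that("screening result is empty with a warning when nothing passes", {
  set.seed(33)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  ft <- feature_table(X, target = rnorm(50))
  fi <- setNames(rep(0.001, 4), paste0("f", 1:4))
  expect_warning(res <- select_variables(ft, selection_config(), fi = fi),
                 "no feature passed")
  expect_length(res$selected, 0)
})

test_that("selection output is collinearity-free and threshold-monotone", {
  ds <- tiny_dataset(seed = 6)
  ft <- build_feature_table(ds$spectra, ds$samples$lpn,
                            sample_ids = ds$samples$sample_id)
  # importance supplied directly: uniform over features, so candidacy is
  # driven by target correlation and the pruning path is exercised heavily
  feats <- colnames(ft$values)
  fi <- setNames(rep(1 / length(feats), length(feats)), feats)
  res <- select_variables(ft, selection_config(), fi = fi)

  expect_gt(length(res$selected), 0)
  if (length(res$selected) > 1) {
    cm <- abs(cor(ft$values[, res$selected]))
    diag(cm) <- 0
    expect_lt(max(cm), 0.8)
  }
  # every dropped candidate is accounted for in the log
  expect_setequal(setdiff(res$candidates, res$selected), res$pruning_log$dropped)

  # raising thresholds never enlarges the candidate set
  res_hi <- select_variables(ft, selection_config(r_threshold = 0.9), fi = fi)
  expect_true(all(res_hi$candidates %in% res$candidates))

  # invariance to feature column order
  perm <- sample(seq_along(feats))
  ft_perm <- feature_table(ft$values[, perm], target = ft$target,
                           sample_ids = ft$sample_ids)
  res_perm <- select_variables(ft_perm, selection_config(), fi = fi[perm])
  expect_setequal(res_perm$selected, res$selected)
})

test_that("the reference variable set resolves to actual band columns", {
  ds <- tiny_dataset(seed = 2)
  ft <- build_feature_table(ds$spectra, ds$samples$lpn,
                            sample_ids = ds$samples$sample_id)
  resolved <- resolve_variable_set(reference_variable_set(), ft)
  expect_length(resolved, 7)
  expect_true(all(resolved %in% colnames(ft$values)))
  expect_true(all(c("PSND", "MTCI", "DCNI") %in% resolved))
  # nominal 775.6 resolves to the closest center on the 224-band grid
  centers <- as.numeric(sub("^B_", "", grep("^B_", resolved, value = TRUE)))
  expect_true(any(abs(centers - 775.6) < 3))
  expect_error(resolve_variable_set("XYZ", ft), class = "contract_error")
})
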