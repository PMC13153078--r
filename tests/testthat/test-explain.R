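named_mat <- function(v, names) matrix(v, nrow = 1, dimnames = list(NULL, names))

test_that("subset enumeration equals the permutation-average oracle", {
  set.seed(41)
  for (p in c(2, 3, 5)) {
    feats <- paste0("x", seq_len(p))
    bg <- matrix(rnorm(6 * p), 6, p, dimnames = list(NULL, feats))
    inst <- matrix(rnorm(p), 1, p, dimnames = list(NULL, feats))
    # a nonlinear model with an interaction
    f <- function(x) x[, 1]^2 + 2 * x[, 1] * x[, 2] + rowSums(sin(x))
    e <- shapley_values(f, bg, inst)
    oracle <- perm_shapley(f, bg, inst[1, ])
    expect_equal(unname(e$values[1, ]), oracle, tolerance = 1e-10,
                 label = paste("p =", p))
  }
})

test_that("efficiency holds on every explained row of a fitted model", {
  set.seed(42)
  X <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] - 0.5 * X[, 2]^2 + rnorm(80, 0, 0.1)
  ft <- feature_table(X, target = y)
  m <- fit_model(ft, "KNN")
  e <- explain_model(m, ft, subset_features(ft, samples = 1:10),
                     max_background = 30, seed = 1)
  preds <- predict(m, subset_features(ft, samples = 1:10))
  expect_equal(e$base_value + rowSums(e$values), preds, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("linear models yield the closed-form attributions", {
  # hand-enumerable case: f = 2 x1 + 3 x2, background (0,0), instance (1,1)
  f <- function(x) 2 * x[, 1] + 3 * x[, 2]
  e <- shapley_values(f, named_mat(c(0, 0), c("x1", "x2")),
                      named_mat(c(1, 1), c("x1", "x2")))
  expect_equal(unname(e$values[1, ]), c(2, 3))
  expect_equal(e$base_value, 0)

  # general closed form: phi_i = beta_i * (x_i - mean background x_i)
  set.seed(43)
  beta <- c(1.5, -2, 0.7)
  flin <- function(x) as.numeric(x %*% beta) + 4
  bg <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, paste0("x", 1:3)))
  inst <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, paste0("x", 1:3)))
  e2 <- shapley_values(flin, bg, inst)
  expected <- sweep(inst, 2, colMeans(bg)) %*% diag(beta)
  expect_equal(unname(e2$values), unname(expected), tolerance = 1e-10)

  # dummy axiom: an ignored feature gets zero everywhere
  fdum <- function(x) 5 * x[, 1]
  e3 <- shapley_values(fdum, bg, inst)
  expect_equal(unname(e3$values[, 2]), c(0, 0))
  expect_equal(unname(e3$values[, 3]), c(0, 0))

  # symmetry: exchangeable features on a symmetric instance share credit
  fsym <- function(x) x[, 1] + x[, 2]
  e4 <- shapley_values(fsym, named_mat(c(0, 0), c("x1", "x2")),
                       named_mat(c(0.8, 0.8), c("x1", "x2")))
  expect_equal(e4$values[1, "x1"], e4$values[1, "x2"])
})

test_that("feature-count and background preconditions are enforced", {
  f <- function(x) rowSums(x)
  wide <- matrix(0, 1, 16, dimnames = list(NULL, paste0("x", 1:16)))
  expect_error(shapley_values(f, wide, wide), class = "combinatorial_limit")
  ok <- named_mat(c(0, 0), c("a", "b"))
  expect_error(shapley_values(f, ok[0, , drop = FALSE], ok),
               class = "contract_error")
})

test_that("ranking orders by mean absolute value with name tie-breaks", {
  e <- structure(list(
    base_value = 0,
    values = matrix(c(0.2, 0.2, -0.05, 0.05, 0.1, -0.1), 2, 3,
                    dimnames = list(c("s1", "s2"), c("f1", "f2", "f3"))),
    feature_names = c("f1", "f2", "f3"),
    sample_ids = c("s1", "s2")), class = "shap_explanation")
  rk <- rank_features(e)
  expect_equal(rk$feature, c("f1", "f3", "f2"))
  expect_equal(rk$mean_abs_shap, c(0.2, 0.1, 0.05))

  e$values[] <- 0
  expect_equal(rank_features(e)$feature, c("f1", "f2", "f3"))

  e1 <- e; e1$values <- e$values[, 1, drop = FALSE]; e1$feature_names <- "f1"
  expect_equal(nrow(rank_features(e1)), 1)
})

test_that("explanation clustering separates well-separated attribution pairs", {
  vals <- rbind(c(0, 0), c(0.01, 0), c(5, 5), c(5.01, 5))
  rownames(vals) <- paste0("s", 1:4)
  e <- structure(list(base_value = 0, values = vals,
                      feature_names = c("f1", "f2"),
                      sample_ids = rownames(vals)),
                 class = "shap_explanation")
  cl <- cluster_samples(e)
  groups <- stats::cutree(cl$hclust, k = 2)
  expect_equal(groups[["s1"]], groups[["s2"]])
  expect_equal(groups[["s3"]], groups[["s4"]])
  expect_false(groups[["s1"]] == groups[["s3"]])

  # duplicated samples merge at height zero
  dup <- e; dup$values <- rbind(vals, vals[1, , drop = FALSE])
  rownames(dup$values)[5] <- "s5"; dup$sample_ids <- rownames(dup$values)
  expect_equal(min(cluster_samples(dup)$height), 0)

  single <- e; single$values <- vals[1, , drop = FALSE]; single$sample_ids <- "s1"
  expect_equal(cluster_samples(single)$order, "s1")
})
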