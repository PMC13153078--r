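# Train/test partitioning, the four regression estimators, and evaluation.

#' Train/test split specification
#'
#' @param train_fraction fraction of samples assigned to training (default 0.8,
#'   i.e. a 4:1 split).
#' @param seed integer seed of the random permutation.
#' @param stratify_by optional character/factor vector (one label per sample)
#'   to stratify the split on, e.g. the nitrogen treatment.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.8, seed = 42, stratify_by = NULL) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must lie strictly between 0 and 1", "invalid_params")
  structure(list(train_fraction = train_fraction, seed = seed,
                 stratify_by = stratify_by),
            class = "split_spec")
}

#' Random train/test partition of a feature table
#'
#' Permutes the samples uniformly at random under the spec's seed and assigns
#' the first `round(train_fraction * N)` to training. The partitions are
#' disjoint and exhaustive; in the pipeline this split happens before feature
#' selection and before augmentation so that no test information leaks into
#' either. With 150 samples at the default 0.8 fraction the split is 120/30.
#'
#' @param table a [feature_table()] with at least 5 samples.
#' @param spec a [split_spec()].
#' @return a list with `train` and `test` (both `feature_table`) and the
#'   integer index vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(table, spec = split_spec()) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "split_spec"))
  n <- nrow(table$values)
  if (n < 5) abort("need at least 5 samples to split", "contract_error")

  train_idx <- with_seed(spec$seed, {
    if (is.null(spec$stratify_by)) {
      perm <- sample.int(n)
      sort(perm[seq_len(round(spec$train_fraction * n))])
    } else {
      strata <- as.character(spec$stratify_by)
      stopifnot(length(strata) == n)
      idx <- unlist(lapply(split(seq_len(n), strata), function(i) {
        p <- if (length(i) > 1) sample(i) else i
        p[seq_len(round(spec$train_fraction * length(i)))]
      }), use.names = FALSE)
      sort(idx)
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_features(table, samples = train_idx),
       test = subset_features(table, samples = test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Fit an LPN regression model
#'
#' Fits one of the four estimators of the pipeline on a training feature
#' table:
#' \itemize{
#'   \item `"MLR"` — multiple linear regression by ordinary least squares
#'     (closed form via QR); a rank-deficient design is an error naming the
#'     offending columns;
#'   \item `"PLSR"` — univariate partial least squares regression by the
#'     NIPALS algorithm on centered data, `n_components` latent components
#'     (default 3, capped at the feature count); with as many components as
#'     full-rank features it reproduces ordinary least squares;
#'   \item `"SVM"` — epsilon-insensitive support vector regression with a
#'     radial-basis kernel ([e1071::svm()]; epsilon 0.1, cost 10) on z-scored
#'     features;
#'   \item `"KNN"` — k-nearest-neighbour regression (default `k = 5`, uniform
#'     weights, Euclidean distance on z-scored features); distance ties are
#'     broken by training-row order.
#' }
#' SVM, KNN and PLSR standardize/center internally using training statistics
#' only; the statistics are stored on the model and applied at prediction.
#'
#' @param train a [feature_table()] with target.
#' @param algorithm one of `"MLR"`, `"PLSR"`, `"SVM"`, `"KNN"`.
#' @param hyperparams optional list: `n_components` (PLSR), `k` (KNN),
#'   `cost`, `epsilon`, `gamma` (SVM).
#' @param seed integer seed (all four fits are deterministic; the seed is
#'   recorded for provenance).
#' @return an object of class `lpn_model`.
#' @export
fit_model <- function(train, algorithm = c("MLR", "PLSR", "SVM", "KNN"),
                      hyperparams = list(), seed = 42) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(train, "feature_table"))
  if (is.null(train$target)) abort("training table has no target", "contract_error")
  X <- train$values
  y <- train$target
  if (nrow(X) == 0) abort("training table is empty", "contract_error")

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)

  fit <- switch(algorithm,
    MLR = {
      Xi <- cbind(`(Intercept)` = 1, X)
      qr_fit <- qr(Xi)
      if (qr_fit$rank < ncol(Xi)) {
        bad <- colnames(Xi)[qr_fit$pivot[(qr_fit$rank + 1):ncol(Xi)]]
        abort(paste("rank-deficient design; offending columns:",
                    paste(bad, collapse = ", ")), "rank_deficiency")
      }
      coefs <- qr.coef(qr_fit, y)
      list(intercept = coefs[1], coefficients = coefs[-1])
    },
    PLSR = {
      ncomp <- hyperparams$n_components %||% 3
      fit_plsr_nipals(X, y, ncomp)
    },
    SVM = with_seed(seed, {
      e1071::svm(x = Xs, y = y, type = "eps-regression", kernel = "radial",
                 cost = hyperparams$cost %||% 10,
                 epsilon = hyperparams$epsilon %||% 0.1,
                 gamma = hyperparams$gamma %||% (1 / ncol(Xs)),
                 scale = FALSE)
    }),
    KNN = {
      k <- hyperparams$k %||% 5
      if (!is_count(k) || k < 1 || k > nrow(Xs))
        abort("`k` must be an integer in [1, n_train]", "invalid_params")
      list(X = Xs, y = y, k = as.integer(k))
    }
  )

  structure(list(algorithm = algorithm, fit = fit,
                 feature_names = colnames(X),
                 mu = mu, sd = sdv, seed = seed,
                 hyperparams = hyperparams, n_train = nrow(X)),
            class = "lpn_model")
}

# PLS1 via NIPALS on centered X and y; returns coefficients on the raw scale.
fit_plsr_nipals <- function(X, y, ncomp) {
  if (!is_count(ncomp) || ncomp < 1)
    abort("`n_components` must be a positive integer", "invalid_params")
  p <- ncol(X)
  ncomp <- min(ncomp, p, nrow(X) - 1L)
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2, xbar)
  f <- y - ybar
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  a <- 0
  for (h in seq_len(ncomp)) {
    w <- crossprod(E, f)                      # p x 1
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break                     # residual carries no covariance
    w <- w / wn
    tt <- E %*% w
    tsq <- sum(tt^2)
    if (tsq < 1e-12) break
    pvec <- crossprod(E, tt) / tsq
    qh <- sum(f * tt) / tsq
    E <- E - tt %*% t(pvec)
    f <- f - qh * tt
    a <- a + 1L
    W[, a] <- w; P[, a] <- pvec; q[a] <- qh
  }
  if (a == 0) {
    beta <- numeric(p)
  } else {
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    q <- q[seq_len(a)]
    beta <- as.numeric(W %*% solve(crossprod(P, W), q))
  }
  list(coefficients = stats::setNames(beta, colnames(X)),
       intercept = ybar - sum(xbar * beta), n_components = a)
}

#' @export
print.lpn_model <- function(x, ...) {
  cat(sprintf("<lpn_model> %s on %d feature(s), %d training sample(s)\n",
              x$algorithm, length(x$feature_names), x$n_train))
  invisible(x)
}

#' Predict LPN for new rows
#'
#' @param object an [fit_model()] result.
#' @param newdata a [feature_table()] or numeric matrix whose columns match
#'   the training features (matched by name when names are present).
#' @param ... unused.
#' @return numeric vector of predicted LPN, % dry mass.
#' @export
predict.lpn_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) newdata$values else {
    m <- as.matrix(newdata); storage.mode(m) <- "double"; m
  }
  if (!is.null(colnames(X))) {
    if (!all(object$feature_names %in% colnames(X)))
      abort("newdata lacks some training features", "contract_error")
    X <- X[, object$feature_names, drop = FALSE]
  } else if (ncol(X) != length(object$feature_names)) {
    abort("newdata has the wrong number of columns", "contract_error")
  }
  if (anyNA(X)) abort("newdata must not contain missing values", "contract_error")

  switch(object$algorithm,
    MLR = as.numeric(object$fit$intercept + X %*% object$fit$coefficients),
    PLSR = as.numeric(object$fit$intercept + X %*% object$fit$coefficients),
    SVM = {
      Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, `/`)
      as.numeric(stats::predict(object$fit, Xs))
    },
    KNN = {
      Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, `/`)
      knn_predict(object$fit$X, object$fit$y, Xs, object$fit$k)
    }
  )
}

# KNN regression; ties in distance broken by training-row order (order() is
# stable in its default method for tied values).
knn_predict <- function(Xtr, ytr, Xnew, k) {
  d2 <- outer(rowSums(Xnew^2), rowSums(Xtr^2), `+`) - 2 * Xnew %*% t(Xtr)
  vapply(seq_len(nrow(Xnew)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    mean(ytr[nb])
  }, numeric(1))
}

#' Accuracy of predictions against observations
#'
#' Computes the coefficient of determination
#' `R2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)` and the root mean
#' square error `RMSE = sqrt(mean((obs - pred)^2))` (% dry mass for LPN).
#'
#' @param pred,obs numeric vectors of equal length >= 2; `obs` must not be
#'   constant (R2 is undefined then).
#' @return an object of class `eval_result`: list with `r2`, `rmse`, `n_test`.
#' @export
evaluate <- function(pred, obs) {
  if (!is.numeric(pred) || !is.numeric(obs) || length(pred) != length(obs) ||
      length(obs) < 2)
    abort("`pred` and `obs` must be numeric vectors of equal length >= 2",
          "contract_error")
  if (anyNA(pred) || anyNA(obs))
    abort("inputs must not contain missing values", "contract_error")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0)
    abort("R2 is undefined for constant observations", "undefined_r2")
  ss_res <- sum((obs - pred)^2)
  structure(list(r2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(mean((obs - pred)^2)),
                 n_test = length(obs)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> R2 = %.4f, RMSE = %.4f %% (n = %d)\n",
              x$r2, x$rmse, x$n_test))
  invisible(x)
}
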