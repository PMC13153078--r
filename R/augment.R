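# Wasserstein-GAN tabular augmentation: small fully connected generator and
# critic trained with the earth-mover objective and weight clipping.

#' WGAN training configuration
#'
#' Hyperparameters of the adversarial pair. The optimization recipe follows
#' the standard small-sample tabular setup: Adam with beta1 = 0, beta2 = 0.9,
#' generator learning rate 1e-4, critic learning rate 2e-4, five critic
#' updates per generator update, a maximum of 200 epochs with batch size 16,
#' and critic weight clipping at 0.01 to enforce the Lipschitz constraint.
#'
#' @param latent_dim dimension of the generator's noise input.
#' @param batch_size samples per optimization step.
#' @param max_epochs maximum training epochs.
#' @param gen_lr,critic_lr Adam learning rates of generator and critic.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param n_critic critic updates per generator update (>= 1).
#' @param clip_value critic weights are clipped to \[-clip_value, clip_value\]
#'   after every critic update (> 0).
#' @param gen_hidden,critic_hidden hidden-layer widths of the two networks.
#' @param seed integer seed governing initialization, batching and noise.
#' @return an object of class `wgan_config`.
#' @export
wgan_config <- function(latent_dim = 16, batch_size = 16, max_epochs = 200,
                        gen_lr = 1e-4, critic_lr = 2e-4, adam_beta1 = 0,
                        adam_beta2 = 0.9, n_critic = 5, clip_value = 0.01,
                        gen_hidden = c(64, 64), critic_hidden = c(64, 64),
                        seed = 42) {
  if (gen_lr <= 0 || critic_lr <= 0)
    abort("learning rates must be positive", "invalid_params")
  if (!is_count(n_critic) || n_critic < 1)
    abort("`n_critic` must be a positive integer", "invalid_params")
  if (!is_number(clip_value) || clip_value <= 0)
    abort("`clip_value` must be positive", "invalid_params")
  if (!is_count(latent_dim) || latent_dim < 1 ||
      !is_count(batch_size) || batch_size < 1 ||
      !is_count(max_epochs) || max_epochs < 1)
    abort("latent_dim, batch_size and max_epochs must be positive integers",
          "invalid_params")
  structure(list(latent_dim = as.integer(latent_dim),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 gen_lr = gen_lr, critic_lr = critic_lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 n_critic = as.integer(n_critic), clip_value = clip_value,
                 gen_hidden = gen_hidden, critic_hidden = critic_hidden,
                 seed = seed),
            class = "wgan_config")
}

# ---- minimal fully connected network with leaky-rectifier activations ----

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He-style scaling for rectifier hidden layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                  sqrt(2 / sizes[l])),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b, alpha = 0.2)
}

# forward pass; hidden layers leaky-ReLU, output linear
mlp_forward <- function(net, X) {
  L <- length(net$W)
  h <- vector("list", L + 1L)
  h[[1L]] <- X
  for (l in seq_len(L)) {
    z <- sweep(h[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
    h[[l + 1L]] <- if (l < L) ifelse(z > 0, z, net$alpha * z) else z
  }
  list(out = h[[L + 1L]], h = h)
}

# back-propagation given dLoss/dOut; returns parameter grads and dLoss/dX
mlp_backward <- function(net, cache, dout) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- dout
  for (l in L:1) {
    if (l < L) delta <- delta * ifelse(cache$h[[l + 1L]] > 0, 1, net$alpha)
    dW[[l]] <- crossprod(cache$h[[l]], delta)
    db[[l]] <- colSums(delta)
    delta <- delta %*% t(net$W[[l]])
  }
  list(dW = dW, db = db, dX = delta)
}

adam_init <- function(net) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero(net$W), vW = zero(net$W),
       mb = zero(net$b), vb = zero(net$b), t = 0L)
}

adam_step <- function(net, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- b1 * state$mW[[l]] + (1 - b1) * grads$dW[[l]]
    state$vW[[l]] <- b2 * state$vW[[l]] + (1 - b2) * grads$dW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (state$mW[[l]] / corr1) / (sqrt(state$vW[[l]] / corr2) + eps)
    state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * grads$db[[l]]
    state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * grads$db[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (state$mb[[l]] / corr1) / (sqrt(state$vb[[l]] / corr2) + eps)
  }
  list(net = net, state = state)
}

clip_params <- function(net, c) {
  # pmin/pmax keep the attributes of their first argument: keep matrices first
  net$W <- lapply(net$W, function(w) pmin(pmax(w, -c), c))
  net$b <- lapply(net$b, function(w) pmin(pmax(w, -c), c))
  net
}

max_abs_params <- function(net) {
  max(vapply(c(net$W, net$b), function(w) max(abs(w)), numeric(1)))
}

# coerce training input to a plain numeric matrix (features + optional target)
as_training_matrix <- function(x) {
  if (inherits(x, "feature_table")) {
    m <- x$values
    if (!is.null(x$target)) m <- cbind(m, lpn = x$target)
    return(m)
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  m
}

#' Train a Wasserstein GAN on tabular training rows
#'
#' Trains a generator/critic pair on the joint distribution of the training
#' rows (selected features plus the LPN target). Columns are z-scored
#' internally using training statistics (inverted on generation). Each
#' generator step minimizing `-mean(D(G(z)))` is preceded by `n_critic` critic
#' steps ascending `mean(D(x)) - mean(D(G(z)))` (implemented by minimizing the
#' negation); critic parameters are clipped to `[-clip_value, clip_value]`
#' after every critic update, which keeps the critic Lipschitz so its
#' real-minus-fake score gap estimates the Wasserstein distance.
#'
#' @param train_rows a [feature_table()] with target, or a numeric matrix /
#'   data frame of feature+target rows (training partition only — never fit
#'   the generator on test rows).
#' @param cfg a [wgan_config()].
#' @return an object of class `wgan_generator`: the fitted generator and
#'   critic, the standardization statistics, per-column training ranges, the
#'   per-epoch loss history (`epoch`, `gen_loss`, `critic_objective`), and
#'   `max_abs_critic_after_update`, the largest absolute critic parameter
#'   observed after any update (always at most `clip_value`).
#' @export
train_wgan <- function(train_rows, cfg = wgan_config()) {
  stopifnot(inherits(cfg, "wgan_config"))
  X <- as_training_matrix(train_rows)
  n <- nrow(X); d <- ncol(X)
  if (n < 2 * cfg$batch_size)
    abort(sprintf("need at least %d training rows, got %d",
                  2 * cfg$batch_size, n), "training_data_error")

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  b <- cfg$batch_size

  with_seed(cfg$seed, {
    gen <- mlp_init(c(cfg$latent_dim, cfg$gen_hidden, d))
    cri <- mlp_init(c(d, cfg$critic_hidden, 1L))
    gen_opt <- adam_init(gen)
    cri_opt <- adam_init(cri)
    steps <- max(1L, n %/% b)
    hist_g <- numeric(cfg$max_epochs)
    hist_c <- numeric(cfg$max_epochs)
    max_abs_after <- 0

    for (epoch in seq_len(cfg$max_epochs)) {
      gl <- 0; cl <- 0
      for (step in seq_len(steps)) {
        for (k in seq_len(cfg$n_critic)) {
          real <- Z[sample.int(n, b), , drop = FALSE]
          zno <- matrix(stats::rnorm(b * cfg$latent_dim), b, cfg$latent_dim)
          fake <- mlp_forward(gen, zno)$out
          fc <- mlp_forward(cri, rbind(real, fake))
          # critic minimizes mean(D(fake)) - mean(D(real))
          dout <- matrix(c(rep(-1 / b, b), rep(1 / b, b)), ncol = 1L)
          grads <- mlp_backward(cri, fc, dout)
          upd <- adam_step(cri, grads, cri_opt, cfg$critic_lr,
                           cfg$adam_beta1, cfg$adam_beta2)
          cri <- clip_params(upd$net, cfg$clip_value)
          cri_opt <- upd$state
          max_abs_after <- max(max_abs_after, max_abs_params(cri))
          if (k == cfg$n_critic) {
            obj <- mean(fc$out[seq_len(b), 1L]) - mean(fc$out[b + seq_len(b), 1L])
            if (!is.finite(obj))
              abort(sprintf("critic objective diverged at epoch %d", epoch),
                    "divergence_error")
            cl <- cl + obj
          }
        }
        # generator step: minimize -mean(D(G(z)))
        zno <- matrix(stats::rnorm(b * cfg$latent_dim), b, cfg$latent_dim)
        fg <- mlp_forward(gen, zno)
        fc <- mlp_forward(cri, fg$out)
        g_loss <- -mean(fc$out)
        if (!is.finite(g_loss))
          abort(sprintf("generator loss diverged at epoch %d", epoch),
                "divergence_error")
        dx <- mlp_backward(cri, fc, matrix(-1 / b, b, 1L))$dX
        g_grads <- mlp_backward(gen, fg, dx)
        updg <- adam_step(gen, g_grads, gen_opt, cfg$gen_lr,
                          cfg$adam_beta1, cfg$adam_beta2)
        gen <- updg$net
        gen_opt <- updg$state
        gl <- gl + g_loss
      }
      hist_g[epoch] <- gl / steps
      hist_c[epoch] <- cl / steps
    }

    structure(list(
      generator = gen, critic = cri, mu = mu, sd = sdv,
      col_min = apply(X, 2, min), col_max = apply(X, 2, max),
      feature_names = colnames(X), latent_dim = cfg$latent_dim,
      n_train = n, config = cfg,
      history = data.frame(epoch = seq_len(cfg$max_epochs),
                           gen_loss = hist_g, critic_objective = hist_c),
      max_abs_critic_after_update = max_abs_after
    ), class = "wgan_generator")
  })
}

#' @export
print.wgan_generator <- function(x, ...) {
  cat(sprintf(
    "<wgan_generator> %d-dim rows, latent %d, trained %d epochs on %d rows\n",
    length(x$feature_names), x$latent_dim, nrow(x$history), x$n_train))
  invisible(x)
}

#' Draw synthetic rows from a trained generator
#'
#' Samples latent Gaussian noise, runs the generator and inverts the internal
#' z-scoring. By default each column is clipped to the training range widened
#' by half the range on each side, which prevents physically absurd values
#' while leaving room for extrapolation.
#'
#' @param g a fitted [train_wgan()] generator.
#' @param n number of synthetic rows (>= 0).
#' @param seed integer seed; the same seed yields bit-identical rows.
#' @param clip clip columns to the widened training range? (default `TRUE`)
#' @return numeric matrix of `n` synthetic rows with the training column names.
#' @export
generate_samples <- function(g, n, seed = 1, clip = TRUE) {
  stopifnot(inherits(g, "wgan_generator"))
  if (!is_count(n)) abort("`n` must be a non-negative integer", "invalid_params")
  d <- length(g$feature_names)
  if (n == 0) {
    out <- matrix(numeric(0), 0, d)
    colnames(out) <- g$feature_names
    return(out)
  }
  with_seed(seed, {
    zno <- matrix(stats::rnorm(n * g$latent_dim), n, g$latent_dim)
    out <- mlp_forward(g$generator, zno)$out
    out <- sweep(sweep(out, 2, g$sd, `*`), 2, g$mu, `+`)
    if (clip) {
      half <- 0.5 * (g$col_max - g$col_min)
      lo <- g$col_min - half
      hi <- g$col_max + half
      out <- pmin(matrix(hi, n, d, byrow = TRUE),
                  pmax(matrix(lo, n, d, byrow = TRUE), out))
    }
    colnames(out) <- g$feature_names
    out
  })
}

#' Augment a training table with synthetic rows
#'
#' Appends `n` generator draws to the real training rows. Real rows are
#' carried over bit-identically; the `origin` flag distinguishes them.
#'
#' @param table the training [feature_table()] (with target) the generator was
#'   fitted on.
#' @param g a fitted [train_wgan()] generator whose columns are the table's
#'   features plus `lpn`.
#' @param n number of synthetic rows.
#' @param seed seed for [generate_samples()].
#' @return a list with `table` (combined `feature_table`, synthetic sample ids
#'   prefixed `G`) and `origin` (character vector, `"real"`/`"synthetic"`).
#' @export
augment_dataset <- function(table, g, n, seed = 1) {
  stopifnot(inherits(table, "feature_table"), inherits(g, "wgan_generator"))
  if (is.null(table$target))
    abort("training table must carry the LPN target", "contract_error")
  expected <- c(colnames(table$values), "lpn")
  if (!identical(g$feature_names, expected))
    abort("generator columns do not match the table's features + target",
          "contract_error")
  syn <- generate_samples(g, n, seed = seed)
  values <- rbind(table$values,
                  syn[, colnames(table$values), drop = FALSE])
  target <- c(table$target, if (n > 0) syn[, "lpn"] else numeric(0))
  ids <- c(table$sample_ids, if (n > 0) paste0("G", seq_len(n)) else character(0))
  rownames(values) <- ids
  list(table = feature_table(values, target = target, sample_ids = ids),
       origin = c(rep("real", nrow(table$values)),
                  rep("synthetic", n)))
}

#' Empirical one-dimensional Wasserstein distance
#'
#' The earth-mover distance between two samples, computed exactly as the
#' integral of the absolute difference of their empirical distribution
#' functions (for equal sample sizes this equals the mean absolute difference
#' of matched order statistics). For two location-shifted copies of the same
#' shape it equals the absolute mean difference.
#'
#' @param x,y non-empty numeric samples.
#' @return a non-negative scalar.
#' @export
wasserstein_1d <- function(x, y) {
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y))
    abort("samples must be non-empty and free of missing values", "contract_error")
  z <- sort(c(x, y))
  if (length(z) < 2) return(0)
  dz <- diff(z)
  grid <- z[-length(z)]
  fx <- findInterval(grid, sort(x)) / length(x)
  fy <- findInterval(grid, sort(y)) / length(y)
  sum(abs(fx - fy) * dz)
}

# two-sample Kolmogorov-Smirnov statistic (max ECDF gap), ties handled exactly
ks_statistic <- function(x, y) {
  z <- sort(unique(c(x, y)))
  fx <- findInterval(z, sort(x)) / length(x)
  fy <- findInterval(z, sort(y)) / length(y)
  max(abs(fx - fy))
}

#' Per-feature diagnostics comparing real and synthetic samples
#'
#' For every feature, reports the means and standard deviations of the two
#' samples, the two-sample Kolmogorov-Smirnov statistic and the empirical
#' one-dimensional Wasserstein distance (see [wasserstein_1d()]).
#'
#' @param real,synthetic numeric matrices with the same number of columns
#'   (feature tables are accepted and include their target as a column).
#' @return a `data.frame` with one row per feature: `feature`, `mean_real`,
#'   `mean_synthetic`, `sd_real`, `sd_synthetic`, `ks`, `wasserstein`.
#' @export
compare_distributions <- function(real, synthetic) {
  r <- as_training_matrix(real)
  s <- as_training_matrix(synthetic)
  if (ncol(r) != ncol(s))
    abort("real and synthetic matrices must have the same feature count",
          "contract_error")
  if (!nrow(r) || !nrow(s))
    abort("both samples must be non-empty", "contract_error")
  feats <- colnames(r) %||% paste0("V", seq_len(ncol(r)))
  data.frame(
    feature = feats,
    mean_real = colMeans(r),
    mean_synthetic = colMeans(s),
    sd_real = apply(r, 2, stats::sd),
    sd_synthetic = apply(s, 2, stats::sd),
    ks = vapply(seq_len(ncol(r)), function(j) ks_statistic(r[, j], s[, j]),
                numeric(1)),
    wasserstein = vapply(seq_len(ncol(r)), function(j)
      wasserstein_1d(r[, j], s[, j]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
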