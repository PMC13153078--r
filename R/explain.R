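# Exact Shapley-value attribution by subset enumeration, feature ranking and
# hierarchical clustering of per-sample explanations.

#' Exact Shapley values by subset enumeration
#'
#' Attributes each prediction to the model's features with exact Shapley
#' values. The value of a coalition S is the interventional (marginal)
#' convention: the mean model prediction over the background rows after
#' replacing the columns in S with the explained instance's values. The
#' Shapley value of feature i is the weighted sum over all coalitions S not
#' containing i of `|S|! (M - |S| - 1)! / M! * (v(S + i) - v(S))`, enumerated
#' exhaustively over all `2^M` coalitions, and the base value is `v(empty)`,
#' the mean background prediction. Efficiency — base value plus all feature
#' values equals the model's prediction — holds by construction and is
#' asserted on every explained row.
#'
#' Exhaustive enumeration is exponential in the feature count, so at most 15
#' features are allowed; the screened variable sets this package produces are
#' far smaller.
#'
#' @param model_predict a function taking a numeric matrix (columns = features)
#'   and returning a numeric vector of predictions, e.g.
#'   `function(x) predict(model, x)`.
#' @param background non-empty numeric matrix of reference rows (typically the
#'   training partition, possibly subsampled).
#' @param instances numeric matrix of rows to explain, same columns as
#'   `background`.
#' @return an object of class `shap_explanation`: `base_value` (scalar),
#'   `values` (instances x features matrix of Shapley values),
#'   `feature_names`, `sample_ids`, `background_ids`, and `predictions`
#'   (model output per explained row).
#' @export
shapley_values <- function(model_predict, background, instances) {
  background <- as.matrix(background)
  instances <- as.matrix(instances)
  if (nrow(background) == 0)
    abort("background must contain at least one row", "contract_error")
  if (ncol(background) != ncol(instances))
    abort("background and instances must share the feature columns",
          "contract_error")
  p <- ncol(instances)
  if (p > 15)
    abort(paste("exact enumeration over 2^M coalitions is limited to 15",
                "features; sub-select variables first"), "combinatorial_limit")
  if (p == 0) abort("need at least one feature", "contract_error")

  n_bg <- nrow(background)
  n_subsets <- 2L^p
  # subset membership: n_subsets x p logical, bit j of mask s
  masks <- 0:(n_subsets - 1L)
  member <- sapply(seq_len(p), function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L)
  member <- matrix(member, nrow = n_subsets)
  sizes <- rowSums(member)
  # Shapley kernel weight for a coalition of size s (feature i absent); the
  # full coalition never plays that role, so its weight slot is unused
  wts <- ifelse(sizes < p,
                factorial(sizes) * factorial(pmax(p - sizes - 1, 0)) / factorial(p),
                0)

  feature_names <- colnames(instances) %||% paste0("x", seq_len(p))
  sample_ids <- rownames(instances) %||% paste0("I", seq_len(nrow(instances)))

  values <- matrix(0, nrow(instances), p,
                   dimnames = list(sample_ids, feature_names))
  base_value <- mean(model_predict(background))
  preds <- numeric(nrow(instances))

  for (i in seq_len(nrow(instances))) {
    inst <- instances[i, ]
    # hybrid rows for all coalitions at once: block s holds the background
    # with coalition-s columns replaced by the instance values
    big <- background[rep(seq_len(n_bg), n_subsets), , drop = FALSE]
    rep_cols <- member[rep(seq_len(n_subsets), each = n_bg), , drop = FALSE]
    inst_mat <- matrix(inst, nrow(big), p, byrow = TRUE)
    big[rep_cols] <- inst_mat[rep_cols]
    colnames(big) <- colnames(background)
    v <- colMeans(matrix(model_predict(big), n_bg, n_subsets))

    for (j in seq_len(p)) {
      absent <- !member[, j]
      with_j <- masks[absent] + bitwShiftL(1L, j - 1L)
      values[i, j] <- sum(wts[absent] * (v[with_j + 1L] - v[absent]))
    }
    preds[i] <- v[n_subsets]  # full coalition = model prediction on the instance
    if (abs(base_value + sum(values[i, ]) - preds[i]) > 1e-8)
      abort(sprintf("efficiency violated on row %d", i), "efficiency_error")
  }

  structure(list(base_value = base_value, values = values,
                 feature_names = feature_names, sample_ids = sample_ids,
                 background_ids = rownames(background) %||%
                   paste0("B", seq_len(n_bg)),
                 predictions = preds),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> %d sample(s) x %d feature(s), base value %.4f\n",
              nrow(x$values), ncol(x$values), x$base_value))
  invisible(x)
}

#' Explain a fitted model on a feature table
#'
#' Convenience wrapper around [shapley_values()] for [fit_model()] objects:
#' the background defaults to the training rows (subsampled to at most
#' `max_background` rows under `seed`) and the instances default to the rows
#' being explained.
#'
#' @param model an [fit_model()] result.
#' @param background_table [feature_table()] of reference rows (training
#'   partition).
#' @param instance_table [feature_table()] of rows to explain (typically the
#'   test partition).
#' @param max_background cap on background rows (default 100); larger
#'   backgrounds are subsampled reproducibly.
#' @param seed seed of the background subsample.
#' @return a `shap_explanation`, see [shapley_values()].
#' @export
explain_model <- function(model, background_table, instance_table,
                          max_background = 100, seed = 42) {
  stopifnot(inherits(model, "lpn_model"),
            inherits(background_table, "feature_table"),
            inherits(instance_table, "feature_table"))
  bg <- background_table$values[, model$feature_names, drop = FALSE]
  if (nrow(bg) > max_background) {
    keep <- with_seed(seed, sort(sample.int(nrow(bg), max_background)))
    bg <- bg[keep, , drop = FALSE]
  }
  inst <- instance_table$values[, model$feature_names, drop = FALSE]
  shapley_values(function(x) predict(model, x), bg, inst)
}

#' Rank features by mean absolute Shapley value
#'
#' @param e a `shap_explanation`.
#' @return a `data.frame` with columns `feature` and `mean_abs_shap`, sorted
#'   in descending importance; exact ties are ordered by feature name.
#' @export
rank_features <- function(e) {
  stopifnot(inherits(e, "shap_explanation"))
  if (!nrow(e$values)) abort("explanation is empty", "contract_error")
  score <- colMeans(abs(e$values))
  o <- order(-score, e$feature_names)
  data.frame(feature = e$feature_names[o], mean_abs_shap = as.numeric(score[o]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchically cluster samples by explanation similarity
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' per-sample Shapley vectors — the ordering used for explanation heatmaps,
#' which places samples with similar attribution patterns next to each other.
#'
#' @param e a `shap_explanation` with at least one sample.
#' @return a list with `order` (sample ids in leaf order), `merge` and
#'   `height` (the agglomeration tree as in [stats::hclust()]), and `hclust`
#'   (the full `hclust` object, `NULL` for a single sample).
#' @export
cluster_samples <- function(e) {
  stopifnot(inherits(e, "shap_explanation"))
  n <- nrow(e$values)
  if (n < 1) abort("explanation is empty", "contract_error")
  if (n == 1)
    return(list(order = e$sample_ids, merge = matrix(numeric(0), 0, 2),
                height = numeric(0), hclust = NULL))
  hc <- stats::hclust(stats::dist(e$values, method = "euclidean"),
                      method = "average")
  list(order = e$sample_ids[hc$order], merge = hc$merge, height = hc$height,
       hclust = hc)
}

#' Write explanation tables to CSV
#'
#' Emits the per-sample Shapley matrix (with the base value as a column), the
#' feature ranking and the clustering leaf order as plain-text files.
#'
#' @param e a `shap_explanation`.
#' @param dir output directory (created if missing).
#' @return character vector of the written paths, invisibly.
#' @export
write_explanation <- function(e, dir) {
  stopifnot(inherits(e, "shap_explanation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(file.path(dir, "shap_values.csv"),
             file.path(dir, "shap_ranking.csv"),
             file.path(dir, "cluster_order.txt"))
  utils::write.csv(data.frame(sample_id = e$sample_ids,
                              base_value = e$base_value, e$values,
                              check.names = FALSE),
                   paths[1], row.names = FALSE)
  utils::write.csv(rank_features(e), paths[2], row.names = FALSE)
  writeLines(cluster_samples(e)$order, paths[3])
  invisible(paths)
}
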