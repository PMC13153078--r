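# Dual-criterion variable screening with collinearity pruning.

#' Screening configuration
#'
#' Thresholds of the dual-criterion screen: a candidate enters if its
#' tree-ensemble feature importance exceeds `fi_threshold` or its absolute
#' Pearson correlation with the LPN target exceeds `r_threshold`; candidate
#' pairs correlated at `|r| >= collinearity_threshold` are then pruned. Two
#' target correlations whose absolute difference is below `comparability_eps`
#' count as "comparable", in which case the pruning tie-break falls back to
#' feature importance.
#'
#' @param fi_threshold importance fraction a candidate must exceed (default 0.02).
#' @param r_threshold absolute target correlation a candidate must exceed
#'   (default 0.75).
#' @param collinearity_threshold inter-feature absolute correlation at or above
#'   which a pair is pruned (default 0.8).
#' @param comparability_eps absolute difference in target correlation below
#'   which two candidates are comparable (default 0.05).
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(fi_threshold = 0.02, r_threshold = 0.75,
                             collinearity_threshold = 0.8,
                             comparability_eps = 0.05) {
  vals <- c(fi_threshold, r_threshold, collinearity_threshold, comparability_eps)
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0 | vals > 1))
    abort("all selection thresholds must lie in [0, 1]", "invalid_params")
  structure(list(fi_threshold = fi_threshold, r_threshold = r_threshold,
                 collinearity_threshold = collinearity_threshold,
                 comparability_eps = comparability_eps),
            class = "selection_config")
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the preconditions the screening stage
#' relies on made explicit: equal lengths of at least 3 and non-constant
#' inputs (the correlation of a constant vector is undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) || length(x) < 3)
    abort("`x` and `y` must be numeric vectors of equal length >= 3",
          "contract_error")
  if (anyNA(x) || anyNA(y))
    abort("inputs must not contain missing values", "contract_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("correlation is undefined for constant input", "undefined_correlation")
  stats::cor(x, y)
}

#' Gradient-boosted feature importance
#'
#' Fits a gradient-boosted regression-tree ensemble (XGBoost) of the LPN
#' target on all features and returns the gain-based importance of every
#' feature, normalized to sum to one. Features never used in a split receive
#' importance zero. Deterministic for a fixed seed (single-threaded).
#'
#' @param table a [feature_table()] with a target.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta boosting rounds, tree depth and learning rate.
#' @return named numeric vector of importances over all features
#'   (non-negative, summing to 1), or all zeros with a warning when the target
#'   is constant.
#' @export
fi_scores <- function(table, seed = 42, nrounds = 200, max_depth = 4, eta = 0.1) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$target))
    abort("feature table has no target; importance needs one", "contract_error")
  if (nrow(table$values) < 10)
    abort("need at least 10 samples for importance estimation", "contract_error")

  feats <- colnames(table$values)
  zero <- stats::setNames(numeric(length(feats)), feats)
  if (stats::sd(table$target) == 0) {
    warning("constant target: all importances are zero", call. = FALSE)
    return(zero)
  }

  booster <- with_seed(seed, {
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(table$values, label = table$target,
                                  nthread = 1),
      nrounds = nrounds, verbose = 0
    )
  })
  imp <- xgboost::xgb.importance(model = booster)
  if (is.null(imp) || nrow(imp) == 0) {
    warning("ensemble made no splits: all importances are zero", call. = FALSE)
    return(zero)
  }
  out <- zero
  out[imp$Feature] <- imp$Gain
  out / sum(out)
}

#' Dual-criterion variable selection with collinearity pruning
#'
#' Implements the screening procedure: a feature becomes a candidate when its
#' ensemble importance exceeds `fi_threshold` or its absolute Pearson
#' correlation with LPN exceeds `r_threshold` (union of the two criteria).
#' Candidates are then pruned iteratively: while any pair has inter-feature
#' `|r| >= collinearity_threshold`, the worst pair (largest `|r|`, ties broken
#' by name order) is resolved by dropping one member — the one with the weaker
#' target correlation; when the two target correlations are comparable
#' (absolute difference below `comparability_eps`) the one with the lower
#' importance is dropped; a residual tie keeps the alphabetically first
#' feature. Every drop is logged.
#'
#' Features with zero variance cannot be correlated with the target and can
#' only enter through the importance criterion.
#'
#' @param table a [feature_table()] with target (the training partition only —
#'   screening on the full dataset leaks test information).
#' @param cfg a [selection_config()].
#' @param seed seed passed to [fi_scores()].
#' @param fi optional precomputed importance vector (skips the ensemble fit).
#' @return an object of class `selection_result`: list with `selected`
#'   (character), `fi` and `r_target` (named vectors over all features),
#'   `candidates`, `pruning_log` (data.frame: feature_a, feature_b, r_between,
#'   rule, dropped) and `config`.
#' @export
select_variables <- function(table, cfg = selection_config(), seed = 42,
                             fi = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "selection_config"))
  if (is.null(table$target))
    abort("feature table has no target", "contract_error")

  feats <- colnames(table$values)
  if (is.null(fi)) fi <- fi_scores(table, seed = seed)
  stopifnot(identical(sort(names(fi)), sort(feats)))
  fi <- fi[feats]

  sds <- apply(table$values, 2, stats::sd)
  r_target <- stats::setNames(rep(NA_real_, length(feats)), feats)
  ok <- sds > 0 & stats::sd(table$target) > 0
  if (any(ok))
    r_target[ok] <- as.numeric(stats::cor(table$values[, ok, drop = FALSE],
                                          table$target))

  pass_fi <- fi > cfg$fi_threshold
  pass_r <- !is.na(r_target) & abs(r_target) > cfg$r_threshold
  candidates <- feats[pass_fi | pass_r]

  log_rows <- list()
  if (length(candidates) == 0) {
    warning("no feature passed either screening criterion", call. = FALSE)
    selected <- character()
  } else if (length(candidates) == 1) {
    selected <- candidates
  } else {
    cmat <- abs(stats::cor(table$values[, candidates, drop = FALSE]))
    diag(cmat) <- 0
    cmat[is.na(cmat)] <- 0  # zero-variance candidates: uncorrelated by convention
    keep <- candidates
    while (length(keep) > 1 && max(cmat) >= cfg$collinearity_threshold) {
      m <- max(cmat)
      hits <- which(cmat == m & upper.tri(cmat), arr.ind = TRUE)
      # tie on |r|: take the pair that is first in (name, name) order
      pair_names <- cbind(rownames(cmat)[hits[, 1]], colnames(cmat)[hits[, 2]])
      pair_sorted <- t(apply(pair_names, 1, sort))
      o <- order(pair_sorted[, 1], pair_sorted[, 2])[1]
      a <- pair_sorted[o, 1]; b <- pair_sorted[o, 2]

      ra <- abs(r_target[a]); rb <- abs(r_target[b])
      ra[is.na(ra)] <- -Inf; rb[is.na(rb)] <- -Inf
      if (abs(ra - rb) >= cfg$comparability_eps) {
        drop <- if (ra >= rb) b else a
        rule <- "weaker target correlation dropped"
      } else if (fi[a] != fi[b]) {
        drop <- if (fi[a] >= fi[b]) b else a
        rule <- "comparable target correlation; lower importance dropped"
      } else {
        drop <- b  # a < b alphabetically by construction
        rule <- "full tie; alphabetically later dropped"
      }
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        feature_a = a, feature_b = b, r_between = m, rule = rule,
        dropped = drop, stringsAsFactors = FALSE)
      keep <- setdiff(keep, drop)
      cmat <- cmat[keep, keep, drop = FALSE]
    }
    selected <- keep
  }

  pruning_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(feature_a = character(), feature_b = character(),
               r_between = numeric(), rule = character(),
               dropped = character(), stringsAsFactors = FALSE)

  structure(list(selected = selected, fi = fi, r_target = r_target,
                 candidates = candidates, pruning_log = pruning_log,
                 config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d candidate(s), %d selected after pruning\n",
              length(x$candidates), length(x$selected)))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result a `selection_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(list(
    selected = result$selected,
    candidates = result$candidates,
    fi = as.list(result$fi),
    r_target = as.list(result$r_target),
    pruning_log = result$pruning_log,
    config = unclass(result$config)
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Reference seven-variable set for LPN estimation
#'
#' A fixed variable list — four narrow bands (near 445, 554, 639 and 776 nm)
#' plus the PSND, MTCI and DCNI indices — reported as informative for rice
#' leaf protein nitrogen in field studies with this sensor class. It lets the
#' modeling and explanation stages run with a known variable set instead of a
#' data-driven screen. Band names are nominal; resolve them against an actual
#' feature table with [resolve_variable_set()].
#'
#' @return character vector of feature names.
#' @export
reference_variable_set <- function() {
  c("B_775.6", "B_444.89", "B_553.58", "PSND", "MTCI", "B_639.48", "DCNI")
}

#' Resolve nominal band names against a feature table
#'
#' Maps each `B_<wavelength>` name to the feature-table band column whose
#' center is closest to the nominal wavelength; index acronyms are passed
#' through unchanged. Duplicates after resolution are removed.
#'
#' @param features character vector of nominal feature names.
#' @param table a [feature_table()] whose band columns are named `B_<center>`.
#' @return character vector of actual column names of `table`.
#' @export
resolve_variable_set <- function(features, table) {
  stopifnot(inherits(table, "feature_table"))
  cols <- colnames(table$values)
  band_cols <- grep("^B_", cols, value = TRUE)
  centers <- as.numeric(sub("^B_", "", band_cols))
  out <- vapply(features, function(f) {
    if (!grepl("^B_", f)) {
      if (!f %in% cols)
        abort(sprintf("feature '%s' not present in the table", f), "contract_error")
      return(f)
    }
    if (f %in% cols) return(f)
    if (!length(band_cols))
      abort("table has no band columns to resolve against", "contract_error")
    band_cols[which.min(abs(centers - as.numeric(sub("^B_", "", f))))]
  }, character(1), USE.NAMES = FALSE)
  unique(out)
}
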