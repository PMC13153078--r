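# End-to-end orchestration: simulate -> preprocess -> features -> split ->
# select -> augment -> fit -> evaluate -> explain, under one seeded config.

#' Pipeline configuration
#'
#' Bundles the sub-configurations of every stage. All randomness derives from
#' `seed`: each stage uses a fixed offset of it (simulation `seed + 1/2`,
#' split `seed + 3`, importance `seed + 4`, WGAN `seed + 5`, generation
#' `seed + 6`, explanation background `seed + 7`), so one integer reproduces
#' the whole run.
#'
#' @param rates,replicates trial design, see [generate_design()].
#' @param lpn an [lpn_params()] object.
#' @param subsamples_per_plot subsamples per plot, see [simulate_lpn()].
#' @param sensor a [sensor_model()].
#' @param smooth_sigma Gaussian denoising bandwidth in band units
#'   (see [gaussian_smooth()]); 0 disables smoothing.
#' @param selection a [selection_config()].
#' @param split a [split_spec()]; its seed is overridden by the master seed.
#' @param wgan a [wgan_config()]; its seed is overridden by the master seed.
#' @param augmentation train a WGAN and fit augmented models? (default `TRUE`)
#' @param n_synthetic synthetic rows to generate (default 1000).
#' @param algorithms subset of `c("MLR", "PLSR", "SVM", "KNN")`.
#' @param variables `"auto"` (data-driven screening) or a character vector of
#'   feature names (nominal band names are resolved with
#'   [resolve_variable_set()]), e.g. [reference_variable_set()].
#' @param explain_instances `"test"` or `"train"`: which partition to explain.
#' @param max_background background cap for [explain_model()].
#' @param seed master seed.
#' @param out_dir optional output directory; when given, every stage artifact
#'   is written there (see [run_pipeline()]).
#' @return an object of class `run_config`.
#' @export
run_config <- function(rates = c(0, 37.5, 75, 112.5, 150, 187.5),
                       replicates = 5, lpn = lpn_params(),
                       subsamples_per_plot = 5, sensor = sensor_model(),
                       smooth_sigma = 1, selection = selection_config(),
                       split = split_spec(), wgan = wgan_config(),
                       augmentation = TRUE, n_synthetic = 1000,
                       algorithms = c("MLR", "PLSR", "SVM", "KNN"),
                       variables = "auto",
                       explain_instances = c("test", "train"),
                       max_background = 100, seed = 42, out_dir = NULL) {
  known <- c("MLR", "PLSR", "SVM", "KNN")
  if (!length(algorithms) || !all(algorithms %in% known))
    abort(paste("unknown algorithm(s):",
                paste(setdiff(algorithms, known), collapse = ", ")),
          "config_error")
  if (!is_count(n_synthetic)) abort("`n_synthetic` must be >= 0", "config_error")
  stopifnot(inherits(lpn, "lpn_params"), inherits(sensor, "sensor_model"),
            inherits(selection, "selection_config"),
            inherits(split, "split_spec"), inherits(wgan, "wgan_config"))
  structure(list(rates = rates, replicates = replicates, lpn = lpn,
                 subsamples_per_plot = subsamples_per_plot, sensor = sensor,
                 smooth_sigma = smooth_sigma, selection = selection,
                 split = split, wgan = wgan, augmentation = augmentation,
                 n_synthetic = n_synthetic, algorithms = algorithms,
                 variables = variables,
                 explain_instances = match.arg(explain_instances),
                 max_background = max_background, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full LPN estimation pipeline
#'
#' Executes every stage in the leakage-safe order: the train/test split is
#' drawn before variable screening, and screening, WGAN training and model
#' fitting only ever see training rows; the test partition is used exactly
#' once, for final evaluation (and, optionally, as the explained instances).
#' This is asserted on sample identities at run time.
#'
#' For every requested algorithm the report contains test-set R2 and RMSE of
#' the model fitted on the original training rows and — when augmentation is
#' on — of the model refitted on training + synthetic rows, together with the
#' absolute and relative R2 improvement
#' (`(R2_aug - R2_orig) / R2_orig * 100`). The best model by test R2 is
#' explained with exact Shapley values.
#'
#' @param cfg a [run_config()].
#' @return a list of class `lpn_run`: `config`, `seeds`, `samples`, `features`
#'   (assembled feature table), `split` (index vectors), `selection`
#'   (`selection_result` or the fixed variable set used), `selected`
#'   (character), `wgan` (fitted generator or `NULL`), `augmented_diagnostics`
#'   (per-feature real-vs-synthetic comparison or `NULL`), `metrics`
#'   (data.frame: algorithm, dataset, r2, rmse), `improvement` (data.frame:
#'   algorithm, r2_original, r2_augmented, delta_r2, relative_improvement_pct),
#'   `best` (algorithm/dataset of the best test R2), `explanation`
#'   (`shap_explanation`), `ranking`, `cluster_order`, and `counts`
#'   (named row counts of every stage).
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- list(lpn = cfg$seed + 1L, spectra = cfg$seed + 2L,
                split = cfg$seed + 3L, importance = cfg$seed + 4L,
                wgan = cfg$seed + 5L, generate = cfg$seed + 6L,
                background = cfg$seed + 7L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- simulate -------------------------------------------------------------
  design <- stage("design", generate_design(cfg$rates, cfg$replicates))
  samples <- stage("lpn", simulate_lpn(design, cfg$lpn,
                                       cfg$subsamples_per_plot,
                                       seed = seeds$lpn))
  spectra <- stage("spectra", with_seed(seeds$spectra, {
    sp <- spectrum_params(lpn_ref = cfg$lpn$lmax)
    lapply(samples$lpn, function(v)
      simulate_spectrum(v, cfg$sensor, seed = NULL, params = sp))
  }))

  # --- preprocess and assemble features ------------------------------------
  if (cfg$smooth_sigma > 0)
    spectra <- stage("smooth",
                     lapply(spectra, gaussian_smooth, sigma_bands = cfg$smooth_sigma))
  features <- stage("features",
                    build_feature_table(spectra, lpn = samples$lpn,
                                        sample_ids = samples$sample_id))

  # --- split before any data-driven choice ----------------------------------
  split_cfg <- cfg$split
  split_cfg$seed <- seeds$split
  parts <- stage("split", split_dataset(features, split_cfg))
  train <- parts$train
  test <- parts$test
  stopifnot(length(intersect(train$sample_ids, test$sample_ids)) == 0)

  # --- variable screening on training rows only -----------------------------
  if (identical(cfg$variables, "auto")) {
    sel <- stage("selection",
                 select_variables(train, cfg$selection, seed = seeds$importance))
    selected <- sel$selected
  } else {
    sel <- NULL
    selected <- stage("selection", resolve_variable_set(cfg$variables, features))
  }
  if (!length(selected))
    stop("pipeline stage 'selection' failed: no variables survived screening",
         call. = FALSE)
  train_sel <- subset_features(train, selected)
  test_sel <- subset_features(test, selected)

  # --- augmentation on training rows only -----------------------------------
  wgan <- NULL; aug_table <- NULL; aug_diag <- NULL
  if (cfg$augmentation) {
    wcfg <- cfg$wgan
    wcfg$seed <- seeds$wgan
    wgan <- stage("wgan", train_wgan(train_sel, wcfg))
    stopifnot(length(intersect(test$sample_ids, train_sel$sample_ids)) == 0)
    aug <- stage("generate",
                 augment_dataset(train_sel, wgan, cfg$n_synthetic,
                                 seed = seeds$generate))
    aug_table <- aug$table
    if (cfg$n_synthetic > 0)
      aug_diag <- compare_distributions(
        train_sel,
        aug_table$values[aug$origin == "synthetic", , drop = FALSE] |>
          cbind(lpn = aug_table$target[aug$origin == "synthetic"]))
  }

  # --- fit and evaluate ------------------------------------------------------
  metric_rows <- list(); models <- list()
  for (algo in cfg$algorithms) {
    m0 <- stage(paste0("fit_", algo), fit_model(train_sel, algo, seed = cfg$seed))
    e0 <- evaluate(predict(m0, test_sel), test_sel$target)
    metric_rows[[length(metric_rows) + 1L]] <- data.frame(
      algorithm = algo, dataset = "original", r2 = e0$r2, rmse = e0$rmse,
      stringsAsFactors = FALSE)
    models[[paste(algo, "original")]] <- m0
    if (cfg$augmentation) {
      m1 <- stage(paste0("fit_", algo, "_augmented"),
                  fit_model(aug_table, algo, seed = cfg$seed))
      e1 <- evaluate(predict(m1, test_sel), test_sel$target)
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        algorithm = algo, dataset = "augmented", r2 = e1$r2, rmse = e1$rmse,
        stringsAsFactors = FALSE)
      models[[paste(algo, "augmented")]] <- m1
    }
  }
  metrics <- do.call(rbind, metric_rows)

  improvement <- NULL
  if (cfg$augmentation) {
    orig <- metrics[metrics$dataset == "original", ]
    augm <- metrics[metrics$dataset == "augmented", ]
    improvement <- data.frame(
      algorithm = orig$algorithm,
      r2_original = orig$r2,
      r2_augmented = augm$r2[match(orig$algorithm, augm$algorithm)],
      stringsAsFactors = FALSE)
    improvement$delta_r2 <- improvement$r2_augmented - improvement$r2_original
    improvement$relative_improvement_pct <-
      100 * improvement$delta_r2 / improvement$r2_original
  }

  # --- explain the best model ------------------------------------------------
  best_row <- metrics[which.max(metrics$r2), ]
  best_model <- models[[paste(best_row$algorithm, best_row$dataset)]]
  inst_table <- if (cfg$explain_instances == "test") test_sel else train_sel
  explanation <- stage("explain",
                       explain_model(best_model, train_sel, inst_table,
                                     max_background = cfg$max_background,
                                     seed = seeds$background))
  ranking <- rank_features(explanation)
  cl <- cluster_samples(explanation)

  run <- structure(list(
    config = cfg, seeds = seeds, design = design, samples = samples,
    features = features,
    split = list(train_idx = parts$train_idx, test_idx = parts$test_idx,
                 train_ids = train$sample_ids, test_ids = test$sample_ids),
    selection = sel, selected = selected, wgan = wgan,
    augmented_diagnostics = aug_diag,
    n_synthetic = if (cfg$augmentation) cfg$n_synthetic else 0L,
    metrics = metrics, improvement = improvement,
    best = list(algorithm = best_row$algorithm, dataset = best_row$dataset),
    explanation = explanation, ranking = ranking, cluster_order = cl$order,
    counts = c(plots = nrow(design), samples = nrow(samples),
               features_bands = sum(grepl("^B_", colnames(features$values))),
               features_indices = sum(!grepl("^B_", colnames(features$values))),
               train = nrow(train$values), test = nrow(test$values),
               selected = length(selected),
               synthetic = if (cfg$augmentation) cfg$n_synthetic else 0L)
  ), class = "lpn_run")

  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' @export
print.lpn_run <- function(x, ...) {
  cat("<lpn_run>\n")
  cat(sprintf("  %d plots, %d samples, %d/%d train/test, %d variable(s): %s\n",
              x$counts["plots"], x$counts["samples"], x$counts["train"],
              x$counts["test"], x$counts["selected"],
              paste(x$selected, collapse = ", ")))
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$improvement)) {
    cat("  relative R2 improvement (%):\n")
    print(x$improvement[, c("algorithm", "relative_improvement_pct")],
          row.names = FALSE)
  }
  cat(sprintf("  best: %s (%s); top feature by mean |SHAP|: %s\n",
              x$best$algorithm, x$best$dataset, x$ranking$feature[1]))
  invisible(x)
}

# write all run artifacts + a manifest to a directory
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_samples_csv(run$samples, file.path(dir, "samples.csv"))
  write_feature_csv(run$features, file.path(dir, "features.csv"))
  if (!is.null(run$selection))
    write_selection_json(run$selection, file.path(dir, "selection.json"))
  utils::write.csv(run$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(run$improvement))
    utils::write.csv(run$improvement, file.path(dir, "improvement.csv"),
                     row.names = FALSE)
  if (!is.null(run$augmented_diagnostics))
    utils::write.csv(run$augmented_diagnostics,
                     file.path(dir, "augmentation_diagnostics.csv"),
                     row.names = FALSE)
  if (!is.null(run$wgan))
    utils::write.csv(run$wgan$history, file.path(dir, "wgan_history.csv"),
                     row.names = FALSE)
  write_explanation(run$explanation, file.path(dir, "shap"))
  manifest <- list(
    seed = run$config$seed, seeds = run$seeds,
    selected = run$selected, counts = as.list(run$counts),
    best = run$best,
    algorithms = run$config$algorithms,
    augmentation = run$config$augmentation,
    n_synthetic = run$config$n_synthetic
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
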