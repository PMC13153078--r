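# Narrow-band vegetation index registry and feature-table assembly.

#' Registry of the twenty narrow-band vegetation indices
#'
#' Returns the definitions of the twenty indices used as candidate predictors
#' of leaf protein nitrogen. Each definition holds the acronym, the nominal
#' wavelengths it requires, and its arithmetic expression over reflectances
#' `R<wavelength>`. Wavelengths are resolved to actual sensor bands with
#' [nearest_band()] at evaluation time.
#'
#' Two expressions are implemented exactly as conventionally printed in the
#' agronomic literature this registry follows, even where a more common
#' canonical variant exists:
#' \itemize{
#'   \item OSAVI: `1.16 * (R800 - R670) / (R800 + R670 + 0.16)`;
#'   \item MSR: `(R800/R760 - 1) / sqrt(R800/R670 + 1)`; the canonical variant
#'     using R670 in the first ratio is available via `msr = "canonical"`;
#'   \item DCNI is a chain of divisions read left-associatively:
#'     `((R720 - R700)/(R700 - R670)) / (R700 - R670 + 0.03)`.
#' }
#'
#' @param msr which modified-simple-ratio variant to register: `"printed"`
#'   (default) or `"canonical"`.
#' @return a named list of index definitions, each a list with `acronym`,
#'   `wavelengths` (nm) and `expression` (a string over `R<wavelength>`).
#' @export
index_registry <- function(msr = c("printed", "canonical")) {
  msr <- match.arg(msr)
  def <- function(acronym, wavelengths, expression)
    list(acronym = acronym, wavelengths = wavelengths, expression = expression)
  defs <- list(
    def("NDVI",   c(800, 670),      "(R800 - R670)/(R800 + R670)"),
    def("DCNI",   c(720, 700, 670), "((R720 - R700)/(R700 - R670))/(R700 - R670 + 0.03)"),
    def("MTCI",   c(750, 710, 680), "(R750 - R710)/(R710 - R680)"),
    def("GNDVI",  c(750, 550),      "(R750 - R550)/(R750 + R550)"),
    def("NDRE",   c(790, 720),      "(R790 - R720)/(R790 + R720)"),
    def("SIPI",   c(800, 445, 680), "(R800 - R445)/(R800 - R680)"),
    def("PRI",    c(570, 530),      "(R570 - R530)/(R570 + R530)"),
    def("SRPI",   c(430, 680),      "R430/R680"),
    def("PSSR",   c(800, 500),      "R800/R500"),
    def("PSRI",   c(680, 500, 750), "(R680 - R500)/R750"),
    def("RARS",   c(760, 500),      "R760/R500"),
    def("GI",     c(554, 677),      "R554/R677"),
    def("PSND",   c(800, 470),      "(R800 - R470)/(R800 + R470)"),
    def("OSAVI",  c(800, 670),      "1.16 * (R800 - R670)/(R800 + R670 + 0.16)"),
    def("RENDVI", c(750, 705),      "(R750 - R705)/(R750 + R705)"),
    def("SR",     c(750, 550),      "R750/R550"),
    def("PBI",    c(810, 560),      "R810/R560"),
    def("LCI",    c(850, 710, 680), "(R850 - R710)/(R850 + R680)"),
    def("NPCI",   c(670, 460),      "(R670 - R460)/(R670 + R460)"),
    if (msr == "printed")
      def("MSR", c(800, 760, 670), "(R800/R760 - 1)/sqrt(R800/R670 + 1)")
    else
      def("MSR", c(800, 670),      "(R800/R670 - 1)/sqrt(R800/R670 + 1)")
  )
  names(defs) <- vapply(defs, `[[`, character(1), "acronym")
  defs
}

#' Dump the index registry as a machine-readable table
#' @param registry output of [index_registry()].
#' @return a `data.frame` with columns `acronym`, `wavelengths_nm`
#'   (comma-separated) and `expression`.
#' @export
registry_table <- function(registry = index_registry()) {
  data.frame(
    acronym = vapply(registry, `[[`, character(1), "acronym"),
    wavelengths_nm = vapply(registry, function(d)
      paste(d$wavelengths, collapse = ","), character(1)),
    expression = vapply(registry, `[[`, character(1), "expression"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Evaluate one vegetation index on a spectrum
#'
#' Resolves each nominal wavelength of the definition to the nearest sensor
#' band and evaluates the index expression on the resolved reflectances. A
#' value that is not finite (a zero denominator anywhere in the expression)
#' is returned as `NA`, the undefined-value marker handled downstream by the
#' feature-table policy.
#'
#' @param s a [spectrum()].
#' @param index an acronym (looked up in `registry`) or a definition list.
#' @param registry registry to look acronyms up in.
#' @return a single numeric value, or `NA` if the index is undefined on `s`.
#' @export
compute_index <- function(s, index, registry = index_registry()) {
  d <- if (is.character(index)) {
    if (!index %in% names(registry))
      abort(sprintf("unknown index acronym '%s'", index), "registry_error")
    registry[[index]]
  } else index
  env <- new.env(parent = baseenv())
  for (w in d$wavelengths) {
    nb <- nearest_band(s, w)
    assign(paste0("R", w), s$reflectance[nb$index], envir = env)
  }
  val <- eval(parse(text = d$expression)[[1]], envir = env)
  if (!is.finite(val)) NA_real_ else val
}

#' Assemble the feature table from spectra and targets
#'
#' Builds the samples-by-features matrix the modeling stages consume: one
#' column per raw sensor band (named `B_<center>`) and/or one column per
#' registry index, with the optional LPN target attached. Samples on which an
#' index is undefined (zero denominator) are handled by `undefined`: the
#' default drops such samples with a warning; `"impute"` replaces the
#' undefined values with the column mean of the defined ones.
#'
#' @param spectra list of [spectrum()] objects sharing one wavelength grid.
#' @param lpn optional numeric target, % dry mass, one value per spectrum.
#' @param include_bands include raw band reflectances as features?
#' @param include_indices include registry indices as features?
#' @param registry index registry, see [index_registry()].
#' @param sample_ids optional character ids; defaults to `S1, S2, ...`.
#' @param undefined policy for undefined index values: `"drop"` or `"impute"`.
#' @return a `feature_table`: list with `values` (numeric matrix with sample
#'   ids as rownames and feature names as colnames), `target` (numeric or
#'   `NULL`) and `sample_ids`.
#' @export
build_feature_table <- function(spectra, lpn = NULL, include_bands = TRUE,
                                include_indices = TRUE,
                                registry = index_registry(),
                                sample_ids = NULL,
                                undefined = c("drop", "impute")) {
  undefined <- match.arg(undefined)
  if (!is.list(spectra) || length(spectra) == 0)
    abort("`spectra` must be a non-empty list of spectrum objects", "empty_input")
  if (!include_bands && !include_indices)
    abort("at least one of bands and indices must be included", "invalid_params")
  wl <- spectra[[1]]$wavelengths
  for (s in spectra)
    if (length(s$wavelengths) != length(wl) || any(s$wavelengths != wl))
      abort("spectra must share one wavelength grid", "grid_mismatch")
  if (!is.null(lpn) && length(lpn) != length(spectra))
    abort("`lpn` must have one value per spectrum", "contract_error")
  ids <- sample_ids %||% paste0("S", seq_along(spectra))
  stopifnot(length(ids) == length(spectra), !anyDuplicated(ids))

  blocks <- list()
  if (include_bands) {
    bands <- do.call(rbind, lapply(spectra, `[[`, "reflectance"))
    colnames(bands) <- band_label(wl)
    blocks <- c(blocks, list(bands))
  }
  if (include_indices) {
    idx <- vapply(spectra, function(s)
      vapply(registry, function(d) compute_index(s, d), numeric(1)),
      numeric(length(registry)))
    idx <- if (length(registry) == 1L) matrix(idx, ncol = 1) else t(idx)
    colnames(idx) <- names(registry)
    blocks <- c(blocks, list(idx))
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- ids
  if (anyDuplicated(colnames(values)))
    abort("feature names must be unique", "contract_error")

  target <- if (!is.null(lpn)) as.numeric(lpn) else NULL
  if (anyNA(values)) {
    bad_cols <- colnames(values)[colSums(is.na(values)) > 0]
    if (undefined == "drop") {
      keep <- rowSums(is.na(values)) == 0
      warning(sprintf(
        "dropped %d sample(s) with undefined index values (%s)",
        sum(!keep), paste(bad_cols, collapse = ", ")), call. = FALSE)
      values <- values[keep, , drop = FALSE]
      ids <- ids[keep]
      if (!is.null(target)) target <- target[keep]
    } else {
      warning(sprintf("mean-imputed undefined values in: %s",
                      paste(bad_cols, collapse = ", ")), call. = FALSE)
      for (j in bad_cols) {
        v <- values[, j]
        values[is.na(v), j] <- mean(v, na.rm = TRUE)
      }
    }
  }
  feature_table(values, target = target, sample_ids = ids)
}

#' Construct a feature table
#'
#' @param values numeric matrix, samples in rows, named features in columns.
#' @param target optional numeric LPN target, one per row.
#' @param sample_ids character ids, one per row.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, target = NULL, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    abort("feature names must be present and unique", "contract_error")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids))
    abort("sample ids must be unique, one per row", "contract_error")
  if (!is.null(target)) {
    target <- as.numeric(target)
    if (length(target) != nrow(values))
      abort("target length must equal the number of rows", "contract_error")
  }
  rownames(values) <- sample_ids
  structure(list(values = values, target = target, sample_ids = sample_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$target)) "" else ", with LPN target"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- data.frame(sample_id = x$sample_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$target)) df$lpn <- x$target
  rownames(df) <- NULL
  df
}

#' Subset a feature table
#' @param table a [feature_table()].
#' @param features character feature names to keep (order preserved).
#' @param samples optional sample ids or logical/integer row index.
#' @return the subset `feature_table`.
#' @export
subset_features <- function(table, features = colnames(table$values),
                            samples = NULL) {
  stopifnot(inherits(table, "feature_table"))
  missing_f <- setdiff(features, colnames(table$values))
  if (length(missing_f))
    abort(paste("unknown features:", paste(missing_f, collapse = ", ")),
          "contract_error")
  rows <- if (is.null(samples)) seq_len(nrow(table$values)) else {
    if (is.character(samples)) match(samples, table$sample_ids) else samples
  }
  feature_table(table$values[rows, features, drop = FALSE],
                target = if (!is.null(table$target)) table$target[rows] else NULL,
                sample_ids = table$sample_ids[rows])
}

#' Write a feature table to CSV
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
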