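# Synthetic nitrogen-rate trial: design, leaf protein nitrogen, canopy spectra.

#' Generate a nitrogen-rate field trial design
#'
#' Builds the plot layout of a randomized nitrogen-rate trial: every fertilizer
#' rate is replicated a fixed number of times, and treatments are labelled
#' N1, N2, ... in ascending rate order. The default design is six rates
#' (0 to 187.5 kg/hm2) with five replicates, i.e. 30 plots.
#'
#' @param rates numeric vector of nitrogen application rates, kg/hm2,
#'   all non-negative.
#' @param replicates number of replicate plots per rate.
#' @return a `data.frame` with one row per plot and columns `plot_id`,
#'   `treatment`, `n_rate`, `replicate`.
#' @examples
#' design <- generate_design()
#' nrow(design) # 30
#' @export
generate_design <- function(rates = c(0, 37.5, 75, 112.5, 150, 187.5),
                            replicates = 5) {
  if (!is_count(replicates))
    abort("`replicates` must be a single non-negative integer", "invalid_design")
  if (replicates > 0 && length(rates) == 0)
    abort("`rates` must be non-empty", "invalid_design")
  if (length(rates) && (!is.numeric(rates) || anyNA(rates) || any(rates < 0)))
    abort("all nitrogen rates must be non-negative numbers", "invalid_design")
  if (anyDuplicated(rates))
    abort("nitrogen rates must be distinct", "invalid_design")

  rates <- sort(rates)
  n <- length(rates) * replicates
  if (n == 0) {
    return(data.frame(plot_id = character(), treatment = character(),
                      n_rate = numeric(), replicate = integer(),
                      stringsAsFactors = FALSE))
  }
  treatment <- rep(paste0("N", seq_along(rates)), each = replicates)
  replicate <- rep(seq_len(replicates), times = length(rates))
  data.frame(
    plot_id = paste0(treatment, "_R", replicate),
    treatment = treatment,
    n_rate = rep(rates, each = replicates),
    replicate = replicate,
    stringsAsFactors = FALSE
  )
}

#' Parameters of the saturating LPN response to nitrogen rate
#'
#' Leaf protein nitrogen (LPN, % of dry mass) responds to fertilizer rate with
#' a monotone, saturating curve; a Michaelis-Menten form is used:
#' `lpn = l0 + (lmax - l0) * rate / (k_half + rate) + noise`.
#' Defaults place LPN in roughly the 1.2-3.2 % dry-mass range typical of rice
#' canopies across a 0-187.5 kg/hm2 nitrogen gradient.
#'
#' @param l0 baseline LPN at zero nitrogen, % dry mass.
#' @param lmax asymptotic LPN at saturating nitrogen, % dry mass.
#' @param k_half nitrogen rate at which half the response is reached, kg/hm2.
#' @param sigma additive Gaussian noise s.d. per subsample, % dry mass.
#' @return an object of class `lpn_params`.
#' @export
lpn_params <- function(l0 = 1.2, lmax = 3.8, k_half = 75, sigma = 0.15) {
  if (!is_number(l0) || !is_number(lmax) || !is_number(k_half) || !is_number(sigma))
    abort("all LPN parameters must be single finite numbers", "invalid_params")
  if (!(lmax > l0 && l0 > 0))
    abort("LPN parameters require lmax > l0 > 0", "invalid_params")
  if (k_half <= 0) abort("`k_half` must be positive", "invalid_params")
  if (sigma < 0) abort("`sigma` must be non-negative", "invalid_params")
  structure(list(l0 = l0, lmax = lmax, k_half = k_half, sigma = sigma),
            class = "lpn_params")
}

#' Simulate leaf protein nitrogen per subsample
#'
#' Draws LPN values for every plot in a design, with `subsamples_per_plot`
#' destructive subsamples per plot (the field protocol samples five points per
#' plot in an X pattern). The expected value follows the saturating response
#' in [lpn_params()]; subsample noise is additive Gaussian, and values are
#' clipped at zero. An optional plot-level random effect can be switched on
#' for robustness experiments.
#'
#' @param design plot table from [generate_design()].
#' @param params an [lpn_params()] object.
#' @param subsamples_per_plot subsamples per plot (default 5).
#' @param seed integer seed for reproducibility.
#' @param plot_sigma s.d. of an optional plot-level Gaussian random effect,
#'   % dry mass (default 0, i.e. off).
#' @return a `data.frame` with columns `sample_id`, `plot_id`, `treatment`,
#'   `n_rate`, `replicate`, `lpn`; one row per subsample
#'   (`nrow(design) * subsamples_per_plot` rows).
#' @examples
#' samples <- simulate_lpn(generate_design(), lpn_params(), seed = 1)
#' nrow(samples) # 150
#' @export
simulate_lpn <- function(design, params = lpn_params(), subsamples_per_plot = 5,
                         seed = 1, plot_sigma = 0) {
  if (!inherits(params, "lpn_params"))
    abort("`params` must be created by lpn_params()", "invalid_params")
  if (!is_count(subsamples_per_plot) || subsamples_per_plot < 1)
    abort("`subsamples_per_plot` must be a positive integer", "invalid_params")
  if (!is_number(plot_sigma) || plot_sigma < 0)
    abort("`plot_sigma` must be a non-negative number", "invalid_params")
  stopifnot(is.data.frame(design),
            all(c("plot_id", "treatment", "n_rate", "replicate") %in% names(design)))

  k <- as.integer(subsamples_per_plot)
  idx <- rep(seq_len(nrow(design)), each = k)
  mu <- with(params, l0 + (lmax - l0) * design$n_rate / (k_half + design$n_rate))

  with_seed(seed, {
    plot_eff <- if (plot_sigma > 0) stats::rnorm(nrow(design), 0, plot_sigma) else
      numeric(nrow(design))
    eps <- if (params$sigma > 0) stats::rnorm(length(idx), 0, params$sigma) else
      numeric(length(idx))
    lpn <- pmax(0, mu[idx] + plot_eff[idx] + eps)
    data.frame(
      sample_id = paste0(design$plot_id[idx], "_S", rep(seq_len(k), times = nrow(design))),
      plot_id = design$plot_id[idx],
      treatment = design$treatment[idx],
      n_rate = design$n_rate[idx],
      replicate = design$replicate[idx],
      lpn = lpn,
      stringsAsFactors = FALSE
    )
  })
}

#' Hyperspectral sensor model
#'
#' Describes the imaging spectrometer: spectral range, band count and
#' multiplicative reflectance noise. The default matches a visible/near-infrared
#' push-broom imager with 224 bands over 400-1000 nm; band centers are evenly
#' spaced across the range.
#'
#' @param lambda_min,lambda_max spectral range, nm.
#' @param n_bands number of bands (>= 2).
#' @param noise_sd s.d. of the multiplicative reflectance noise factor
#'   (unitless; default 0.01, i.e. 1 % radiometric noise).
#' @return an object of class `sensor_model`.
#' @export
sensor_model <- function(lambda_min = 400, lambda_max = 1000, n_bands = 224,
                         noise_sd = 0.01) {
  if (!is_number(lambda_min) || !is_number(lambda_max) || lambda_min >= lambda_max)
    abort("need lambda_min < lambda_max", "invalid_params")
  if (!is_count(n_bands) || n_bands < 2)
    abort("`n_bands` must be an integer >= 2", "invalid_params")
  if (!is_number(noise_sd) || noise_sd < 0)
    abort("`noise_sd` must be non-negative", "invalid_params")
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max,
                 n_bands = as.integer(n_bands), noise_sd = noise_sd),
            class = "sensor_model")
}

#' Band centers of a sensor model
#' @param sensor a [sensor_model()].
#' @return numeric vector of band-center wavelengths, nm, strictly ascending.
#' @export
band_centers <- function(sensor) {
  seq(sensor$lambda_min, sensor$lambda_max, length.out = sensor$n_bands)
}

#' Construct a reflectance spectrum
#'
#' @param wavelengths band-center wavelengths in nm, strictly ascending.
#' @param reflectance reflectance values in \[0, 1\], same length.
#' @return an object of class `spectrum`: a list with elements `wavelengths`
#'   and `reflectance`.
#' @export
spectrum <- function(wavelengths, reflectance) {
  if (!is.numeric(wavelengths) || !is.numeric(reflectance))
    abort("wavelengths and reflectance must be numeric", "invalid_spectrum")
  if (length(wavelengths) != length(reflectance))
    abort("wavelengths and reflectance must have equal length", "invalid_spectrum")
  if (anyNA(wavelengths) || anyNA(reflectance))
    abort("spectrum must not contain missing values", "invalid_spectrum")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    abort("wavelengths must be strictly ascending", "invalid_spectrum")
  if (any(reflectance < 0 | reflectance > 1))
    abort("reflectance must lie in [0, 1]", "invalid_spectrum")
  structure(list(wavelengths = as.numeric(wavelengths),
                 reflectance = as.numeric(reflectance)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bands, %.1f-%.1f nm, reflectance %.3f-%.3f\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' Constants of the canopy reflectance generator
#'
#' The simulated canopy spectrum is a two-regime mixture: a visible regime
#' dominated by pigment absorption and a near-infrared (NIR) plateau, blended
#' by a logistic red-edge transition whose inflection shifts to longer
#' wavelengths as canopy chlorophyll (proxied by LPN) increases. This is the
#' mechanism that makes red-edge indices informative about nitrogen status.
#'
#' With chlorophyll proxy `c = clamp(lpn / lpn_ref, 0, 1)`:
#' \itemize{
#'   \item red-edge position `lambda_re = 700 + 15 c` nm, logistic width 10 nm;
#'   \item NIR plateau `R_nir = 0.40 + 0.10 c`;
#'   \item visible floor 0.05 with a green peak at 550 nm that is damped by
#'     chlorophyll and a red absorption dip at 670 nm that deepens with
#'     chlorophyll, floored at 0.01.
#' }
#'
#' @param lpn_ref LPN value mapped to chlorophyll proxy 1 (% dry mass);
#'   defaults to the `lmax` of [lpn_params()].
#' @param lambda_re0 red-edge position at zero chlorophyll, nm.
#' @param re_shift red-edge shift per unit chlorophyll proxy, nm.
#' @param sigma_re logistic red-edge width, nm.
#' @param nir0,nir_gain NIR plateau intercept and chlorophyll gain.
#' @param vis_base visible baseline reflectance.
#' @param green_amp,green_center,green_width green-peak amplitude, center (nm),
#'   Gaussian width (nm).
#' @param green_damp fractional damping of the green peak at proxy 1.
#' @param red_amp,red_center,red_width red absorption-dip amplitude at proxy 1,
#'   center (nm), Gaussian width (nm).
#' @param vis_floor lower bound of visible reflectance.
#' @return a list of generator constants.
#' @export
spectrum_params <- function(lpn_ref = 3.8, lambda_re0 = 700, re_shift = 15,
                            sigma_re = 10, nir0 = 0.40, nir_gain = 0.10,
                            vis_base = 0.05, green_amp = 0.06,
                            green_center = 550, green_width = 25,
                            green_damp = 0.6, red_amp = 0.035,
                            red_center = 670, red_width = 20,
                            vis_floor = 0.01) {
  out <- as.list(environment())
  if (!all(vapply(out, is_number, logical(1))))
    abort("all spectrum parameters must be single finite numbers", "invalid_params")
  if (lpn_ref <= 0) abort("`lpn_ref` must be positive", "invalid_params")
  out
}

#' Simulate a canopy reflectance spectrum for a given LPN
#'
#' Evaluates the generative model of [spectrum_params()] on the band grid of a
#' [sensor_model()], applies multiplicative Gaussian noise
#' (factor ~ Normal(1, noise_sd^2)) and clips the result to \[0, 1\].
#'
#' @param lpn leaf protein nitrogen, % dry mass, non-negative.
#' @param sensor a [sensor_model()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param params generator constants from [spectrum_params()].
#' @return a [spectrum()] with `sensor$n_bands` bands.
#' @export
simulate_spectrum <- function(lpn, sensor = sensor_model(), seed = NULL,
                              params = spectrum_params()) {
  if (!is_number(lpn) || lpn < 0)
    abort("`lpn` must be a single non-negative number", "invalid_params")
  wl <- band_centers(sensor)
  refl <- canopy_reflectance(lpn, wl, params)
  noisy <- with_seed(seed, {
    if (sensor$noise_sd > 0)
      refl * stats::rnorm(length(refl), 1, sensor$noise_sd)
    else refl
  })
  spectrum(wl, pmin(1, pmax(0, noisy)))
}

# Noise-free canopy reflectance at given wavelengths (nm).
canopy_reflectance <- function(lpn, wl, params = spectrum_params()) {
  p <- params
  c_chl <- min(max(lpn / p$lpn_ref, 0), 1)
  lambda_re <- p$lambda_re0 + p$re_shift * c_chl
  s <- 1 / (1 + exp(-(wl - lambda_re) / p$sigma_re))
  r_nir <- p$nir0 + p$nir_gain * c_chl
  r_vis <- p$vis_base +
    p$green_amp * exp(-(wl - p$green_center)^2 / (2 * p$green_width^2)) * (1 - p$green_damp * c_chl) -
    p$red_amp * c_chl * exp(-(wl - p$red_center)^2 / (2 * p$red_width^2))
  r_vis <- pmax(p$vis_floor, r_vis)
  r_nir * s + r_vis * (1 - s)
}

#' Simulate a full trial dataset: design, LPN samples and canopy spectra
#'
#' Convenience wrapper producing everything downstream stages consume: the
#' plot design, the per-subsample LPN table and one canopy spectrum per
#' subsample, all reproducible from a single seed.
#'
#' @param rates,replicates passed to [generate_design()].
#' @param params an [lpn_params()] object.
#' @param subsamples_per_plot subsamples per plot.
#' @param sensor a [sensor_model()].
#' @param spec_params constants from [spectrum_params()].
#' @param seed master seed; LPN noise and spectral noise use derived streams.
#' @param plot_sigma optional plot-level LPN noise s.d. (see [simulate_lpn()]).
#' @return a list with elements `design`, `samples` (LPN table) and `spectra`
#'   (list of [spectrum()] objects, one per sample row).
#' @export
simulate_dataset <- function(rates = c(0, 37.5, 75, 112.5, 150, 187.5),
                             replicates = 5, params = lpn_params(),
                             subsamples_per_plot = 5, sensor = sensor_model(),
                             spec_params = spectrum_params(lpn_ref = params$lmax),
                             seed = 1, plot_sigma = 0) {
  design <- generate_design(rates, replicates)
  samples <- simulate_lpn(design, params, subsamples_per_plot,
                          seed = seed, plot_sigma = plot_sigma)
  spectra <- with_seed(seed + 1L, {
    lapply(samples$lpn, function(v)
      simulate_spectrum(v, sensor, seed = NULL, params = spec_params))
  })
  list(design = design, samples = samples, spectra = spectra)
}

#' Write the sample table to CSV
#' @param samples table from [simulate_lpn()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Write spectra to a wide CSV (one column per band)
#'
#' Columns are `sample_id` followed by one reflectance column per band, named
#' `B_<wavelength>` with the center rounded to two decimals.
#'
#' @param spectra list of [spectrum()] objects sharing one wavelength grid.
#' @param sample_ids character vector, one id per spectrum.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, sample_ids, path) {
  stopifnot(length(spectra) == length(sample_ids), length(spectra) > 0)
  wl <- spectra[[1]]$wavelengths
  mat <- do.call(rbind, lapply(spectra, function(s) {
    if (!isTRUE(all.equal(s$wavelengths, wl)))
      abort("spectra must share one wavelength grid", "grid_mismatch")
    s$reflectance
  }))
  colnames(mat) <- band_label(wl)
  utils::write.csv(cbind(data.frame(sample_id = sample_ids), as.data.frame(mat)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from the wide CSV format of [write_spectra_csv()]
#' @param path CSV file path.
#' @return list with `sample_ids` and `spectra` (list of [spectrum()]).
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  band_cols <- grep("^B_", names(df), value = TRUE)
  wl <- as.numeric(sub("^B_", "", band_cols))
  spectra <- lapply(seq_len(nrow(df)), function(i)
    spectrum(wl, as.numeric(df[i, band_cols])))
  list(sample_ids = as.character(df$sample_id), spectra = spectra)
}

# Canonical band column label: wavelength rounded to 2 decimals, no trailing zeros.
band_label <- function(wl) paste0("B_", vapply(round(wl, 2), function(x)
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE), character(1)))
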