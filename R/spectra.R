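# Spectral preprocessing: ROI averaging, Gaussian denoising, band resolution.

#' Mean spectrum of a region of interest
#'
#' Averages the reflectance of all pixel spectra in a region of interest (ROI)
#' band by band, the standard way a plot-level canopy spectrum is extracted
#' from imagery.
#'
#' @param pixels non-empty list of [spectrum()] objects sharing one
#'   wavelength grid.
#' @return a [spectrum()] with the per-band arithmetic mean.
#' @export
roi_mean <- function(pixels) {
  if (!is.list(pixels) || length(pixels) == 0)
    abort("ROI must contain at least one pixel spectrum", "empty_input")
  wl <- pixels[[1]]$wavelengths
  for (s in pixels) {
    if (!inherits(s, "spectrum"))
      abort("all ROI pixels must be spectrum objects", "empty_input")
    if (length(s$wavelengths) != length(wl) || any(s$wavelengths != wl))
      abort("ROI pixels must share one wavelength grid", "grid_mismatch")
  }
  refl <- Reduce(`+`, lapply(pixels, `[[`, "reflectance")) / length(pixels)
  spectrum(wl, refl)
}

#' Gaussian smoothing along the band axis
#'
#' Denoises a spectrum by discrete convolution with a Gaussian kernel of
#' standard deviation `sigma_bands` (in band units, not nm). The kernel is
#' truncated at four standard deviations and normalized to unit sum; edges are
#' handled by symmetric reflection of the spectrum, so a constant spectrum is
#' returned unchanged and the overall signal mean is conserved.
#'
#' @param s a [spectrum()].
#' @param sigma_bands kernel standard deviation in band units (>= 0); 0
#'   returns the input unchanged.
#' @return the smoothed [spectrum()].
#' @export
gaussian_smooth <- function(s, sigma_bands = 1) {
  stopifnot(inherits(s, "spectrum"))
  if (!is_number(sigma_bands) || sigma_bands < 0)
    abort("`sigma_bands` must be a single non-negative number", "invalid_params")
  if (sigma_bands == 0) return(s)

  x <- s$reflectance
  n <- length(x)
  r <- ceiling(4 * sigma_bands)
  kern <- stats::dnorm(-r:r, sd = sigma_bands)
  kern <- kern / sum(kern)

  # symmetric (edge-inclusive) reflection padding
  left <- x[pmin(n, pmax(1, r:1))]
  right <- x[pmin(n, pmax(1, n:(n - r + 1)))]
  padded <- c(left, x, right)
  sm <- as.numeric(stats::filter(padded, kern, sides = 2))[(r + 1):(r + n)]
  spectrum(s$wavelengths, pmin(1, pmax(0, sm)))
}

#' Resolve a wavelength to the nearest sensor band
#'
#' Index formulas are written in terms of nominal wavelengths (for example
#' R800) that rarely coincide with the sensor's actual band centers; this
#' resolves a target wavelength to the closest center. Exact ties go to the
#' lower wavelength. Targets farther than one band spacing outside the grid
#' are rejected.
#'
#' @param s a [spectrum()].
#' @param target_nm wavelength to resolve, nm.
#' @return a list with `index` (1-based band index) and `wavelength`
#'   (the actual band center, nm).
#' @export
nearest_band <- function(s, target_nm) {
  stopifnot(inherits(s, "spectrum"))
  if (!is_number(target_nm))
    abort("`target_nm` must be a single finite number", "out_of_range")
  wl <- s$wavelengths
  delta <- if (length(wl) > 1) stats::median(diff(wl)) else 0
  if (target_nm < min(wl) - delta || target_nm > max(wl) + delta)
    abort(sprintf("wavelength %.2f nm is outside the sensor range [%.2f, %.2f] +/- %.2f",
                  target_nm, min(wl), max(wl), delta), "out_of_range")
  # which.min returns the first minimizer; wavelengths ascend, so exact ties
  # resolve toward the lower wavelength as documented
  i <- which.min(abs(wl - target_nm))
  list(index = i, wavelength = wl[i])
}
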