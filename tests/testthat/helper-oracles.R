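# Independent oracle implementations used to cross-check package code.
# These deliberately avoid the code paths they verify.

# Shapley values as the average marginal contribution over all |M|! feature
# orderings -- the permutation definition, independent of the subset-sum
# implementation in the package.
perm_shapley <- function(predict_fun, background, instance) {
  p <- length(instance)
  background <- as.matrix(background)
  v <- function(S) {
    hyb <- background
    if (length(S)) hyb[, S] <- matrix(instance[S], nrow(hyb), length(S), byrow = TRUE)
    mean(predict_fun(hyb))
  }
  perms <- perms_of(seq_len(p))
  phi <- numeric(p)
  for (ord in perms) {
    prev <- v(integer(0))
    S <- integer(0)
    for (j in ord) {
      S <- c(S, j)
      cur <- v(S)
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(perms)
}

# all permutations of a vector (tiny n only)
perms_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perms_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# brute-force nearest band: scan every center, first minimum wins
brute_nearest <- function(wavelengths, target) {
  d <- abs(wavelengths - target)
  which(d == min(d))[1]
}

# direct O(n^2) Gaussian convolution with symmetric edge reflection
brute_gaussian_smooth <- function(x, sigma) {
  n <- length(x)
  r <- ceiling(4 * sigma)
  kern <- dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  pad <- c(x[r:1], x, x[n:(n - r + 1)])
  sapply(seq_len(n), function(i) sum(pad[i:(i + 2 * r)] * kern))
}

# spectrum on a grid that contains the exact wavelengths needed by the index
# formulas, with chosen reflectance values at those wavelengths
toy_index_spectrum <- function(values) {
  wl <- sort(as.numeric(names(values)))
  spectrum(wl, as.numeric(values[as.character(wl)]))
}

# all nominal wavelengths any registry index refers to
index_wavelengths <- function() {
  sort(unique(unlist(lapply(index_registry(), `[[`, "wavelengths"))))
}

# flat spectrum covering every index wavelength
flat_index_spectrum <- function(value = 0.5) {
  wl <- index_wavelengths()
  spectrum(wl, rep(value, length(wl)))
}

# a strictly positive, non-flat spectrum on the index grid
bumpy_index_spectrum <- function(seed = 1) {
  wl <- index_wavelengths()
  set.seed(seed)
  spectrum(wl, runif(length(wl), 0.05, 0.95))
}

# small seeded trial dataset shared across tests (cheap: 3 rates x 2 reps)
tiny_dataset <- function(seed = 1, noise_sd = 0.01) {
  simulate_dataset(rates = c(0, 75, 187.5), replicates = 2,
                   subsamples_per_plot = 2,
                   sensor = sensor_model(noise_sd = noise_sd), seed = seed)
}
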