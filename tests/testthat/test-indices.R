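test_that("every registry formula reproduces its hand-computed value", {
  wl <- index_wavelengths()
  # distinct reflectances at every nominal wavelength, keyed by wavelength
  R <- setNames(seq(0.10, 0.90, length.out = length(wl)), as.character(wl))
  s <- toy_index_spectrum(R)
  g <- function(x) unname(R[as.character(x)])

  expected <- c(
    NDVI   = (g(800) - g(670)) / (g(800) + g(670)),
    DCNI   = ((g(720) - g(700)) / (g(700) - g(670))) / (g(700) - g(670) + 0.03),
    MTCI   = (g(750) - g(710)) / (g(710) - g(680)),
    GNDVI  = (g(750) - g(550)) / (g(750) + g(550)),
    NDRE   = (g(790) - g(720)) / (g(790) + g(720)),
    SIPI   = (g(800) - g(445)) / (g(800) - g(680)),
    PRI    = (g(570) - g(530)) / (g(570) + g(530)),
    SRPI   = g(430) / g(680),
    PSSR   = g(800) / g(500),
    PSRI   = (g(680) - g(500)) / g(750),
    RARS   = g(760) / g(500),
    GI     = g(554) / g(677),
    PSND   = (g(800) - g(470)) / (g(800) + g(470)),
    OSAVI  = 1.16 * (g(800) - g(670)) / (g(800) + g(670) + 0.16),
    RENDVI = (g(750) - g(705)) / (g(750) + g(705)),
    SR     = g(750) / g(550),
    PBI    = g(810) / g(560),
    LCI    = (g(850) - g(710)) / (g(850) + g(680)),
    NPCI   = (g(670) - g(460)) / (g(670) + g(460)),
    MSR    = (g(800) / g(760) - 1) / sqrt(g(800) / g(670) + 1)
  )
  reg <- index_registry()
  expect_setequal(names(reg), names(expected))
  for (a in names(expected))
    expect_equal(compute_index(s, a), unname(expected[a]),
                 tolerance = 1e-12, label = a)

  # canonical MSR variant behind the switch
  reg_c <- index_registry(msr = "canonical")
  expect_equal(compute_index(s, "MSR", reg_c),
               (g(800) / g(670) - 1) / sqrt(g(800) / g(670) + 1),
               tolerance = 1e-12)
})

test_that("specific hand evaluations and undefined-value marking", {
  flat <- flat_index_spectrum(0.5)
  expect_equal(compute_index(flat, "NDVI"), 0)
  # zero denominator chain in DCNI on a flat spectrum is undefined
  expect_true(is.na(compute_index(flat, "DCNI")))

  # NDVI with R800 = 0.50, R670 = 0.05
  vals <- setNames(rep(0.5, length(index_wavelengths())),
                   as.character(index_wavelengths()))
  vals["670"] <- 0.05
  expect_equal(compute_index(toy_index_spectrum(vals), "NDVI"), 0.45 / 0.55,
               tolerance = 1e-12)

  expect_error(compute_index(flat, "NOPE"), class = "registry_error")
})

test_that("index families satisfy their algebraic invariants", {
  for (seed in 1:5) {
    s <- bumpy_index_spectrum(seed)
    # all 20 evaluate without error and finite on positive non-flat spectra
    vals <- vapply(names(index_registry()), function(a) compute_index(s, a),
                   numeric(1))
    expect_true(all(is.finite(vals)))

    # normalized-difference indices bounded in [-1, 1]
    for (a in c("NDVI", "GNDVI", "NDRE", "PRI", "PSND", "RENDVI", "NPCI"))
      expect_true(abs(vals[a]) <= 1, label = paste(a, "bounded, seed", seed))

    # pure ratio indices invariant to global scaling of the spectrum
    s_scaled <- spectrum(s$wavelengths, 0.5 * s$reflectance)
    for (a in c("SRPI", "PSSR", "RARS", "GI", "SR", "PBI"))
      expect_equal(compute_index(s_scaled, a), vals[[a]], tolerance = 1e-12,
                   label = paste(a, "scale-invariant, seed", seed))
  }
})

test_that("feature table assembles bands and indices with the row contract", {
  ds <- tiny_dataset(seed = 2)
  ft <- build_feature_table(ds$spectra, ds$samples$lpn,
                            sample_ids = ds$samples$sample_id)
  expect_s3_class(ft, "feature_table")
  expect_equal(ncol(ft$values), 224 + 20)
  expect_equal(nrow(ft$values), nrow(ds$samples))
  expect_equal(ft$sample_ids, ds$samples$sample_id)  # row order preserved
  expect_false(anyNA(ft$values))

  only_idx <- build_feature_table(ds$spectra, include_bands = FALSE)
  expect_equal(ncol(only_idx$values), 20)
  only_bands <- build_feature_table(ds$spectra, include_indices = FALSE)
  expect_equal(ncol(only_bands$values), 224)

  other <- spectrum(seq(400, 900, length.out = 10), rep(0.5, 10))
  expect_error(build_feature_table(c(ds$spectra[1], list(other))),
               class = "grid_mismatch")
})

test_that("undefined index values follow the configured policy", {
  wl <- index_wavelengths()
  flat <- flat_index_spectrum(0.5)   # DCNI undefined here
  good <- bumpy_index_spectrum(3)

  expect_warning(
    dropped <- build_feature_table(list(good, flat, good), lpn = c(1, 2, 3),
                                   include_bands = FALSE),
    "dropped")
  expect_equal(nrow(dropped$values), 2)
  expect_equal(dropped$target, c(1, 3))

  expect_warning(
    imputed <- build_feature_table(list(good, flat, good), lpn = c(1, 2, 3),
                                   include_bands = FALSE,
                                   undefined = "impute"),
    "imputed")
  expect_equal(nrow(imputed$values), 3)
  expect_false(anyNA(imputed$values))
  # imputed value is the mean of the defined entries
  expect_equal(imputed$values[2, "DCNI"], compute_index(good, "DCNI"))
})
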