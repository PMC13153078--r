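Package: lpnspec
Title: Leaf Protein Nitrogen Estimation from Canopy Hyperspectral Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for estimating rice leaf protein
    nitrogen (LPN, percent of dry mass) from canopy reflectance spectra.
    Provides a synthetic generator for a nitrogen-rate field trial and its
    canopy spectra, spectral preprocessing (region-of-interest averaging,
    Gaussian denoising, nearest-band wavelength resolution), a registry of
    twenty narrow-band vegetation indices, dual-criterion variable screening
    (gradient-boosted feature importance plus Pearson correlation) with
    collinearity pruning, Wasserstein-GAN tabular data augmentation, four
    regression estimators (multiple linear regression, partial least squares,
    support vector machine, k-nearest neighbours), and exact Shapley-value
    model explanation with feature ranking and hierarchical clustering of
    per-sample attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
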