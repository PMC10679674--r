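Package: vitaspec
Title: Hyperspectral Imaging Chemometrics for Seed Vitality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting seed vitality (seedling height)
    from hyperspectral images of seed plates: reflectance calibration against
    white/dark reference frames, per-seed spectrum and band-image extraction
    from ENVI cubes, spectral pretreatments (Savitzky-Golay smoothing,
    standard normal variate, multiplicative scatter correction), feature
    wavelength selection by the successive projections algorithm (SPA) and
    competitive adaptive reweighted sampling (CARS), Otsu/connected-component
    seed segmentation scored by pixel accuracy and mean IoU, gray-level
    co-occurrence matrix (GLCM) texture features, SPXY sample partitioning,
    spectral-image feature fusion, and regression by partial least squares,
    support vector regression and a one-dimensional convolutional network.
    Ships a synthetic plate generator with planted, recoverable vitality
    signal so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    EBImage,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
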