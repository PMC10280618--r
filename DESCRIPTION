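Package: glucofuse
Title: Non-Invasive Blood Glucose Estimation from Multi-Wavelength PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A per-subject pipeline for estimating blood glucose from
    multi-wavelength photoplethysmography (PPG). Provides singular spectrum
    analysis (SSA) bit-plane denoising of PPG waveforms, extraction of a
    103-feature vector (meal timing, blood pressure, near-infrared absorption
    statistics, and time- and frequency-domain heart rate variability),
    unit-energy normalisation, cubic-polynomial smoothing of features or
    reference glucose under least-squares, least-absolute-deviation and
    minimax criteria (the latter two solved as linear programs), random-forest
    feature selection and regression, and a fusion rule that partitions the
    sorted validation glucose axis into regions and assigns each region the
    smoothing criterion that wins there. Evaluation includes Pearson R,
    MAE, RMSE, MARD and Clarke error grid analysis, plus a synthetic
    multi-wavelength PPG generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    boot,
    randomForest,
    e1071,
    kernlab,
    dplyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
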