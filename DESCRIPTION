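Package: ramantriage
Title: Serum Raman Spectral Classification and Diagnostic Accuracy for
    Cancer Triage Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, preprocessing and evaluation pipeline for serum
    Raman spectroscopy triage studies of colorectal cancer. Generates
    synthetic cohorts of serum-like spectra with known ground truth,
    implements the standard spectral preprocessing chain (wavenumber
    calibration, binning, Savitzky-Golay smoothing, baseline subtraction,
    normalisation), builds propensity-score matched case-control training
    sets, fits random-forest classifiers with patient-grouped repeated
    cross-validation and per-patient probability aggregation, and reports
    diagnostic accuracy (sensitivity, specificity, AUC) with exact
    Clopper-Pearson confidence intervals, stage-stratified sensitivity and
    prevalence-adjusted sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    minpack.lm,
    jsonlite,
    ranger,
    readr,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
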