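Package: wearhrv
Title: 24-Hour Heart Rate Variability from Semi-Continuous Wearable Heart-Rate Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the 24-hour heart rate variability metric SDNN24 from the
    kind of windowed, semi-continuous heart-rate measures that wrist-worn
    wearable devices emit. Provides beat-annotation I/O, outlier and ectopic
    beat preprocessing with quadratic interpolation, the windowed time-domain
    estimator family (SDNN24, SDNNi24, SDANN24, SDANNHR24) with a calibrated
    photoplethysmography noise model, Lomb-Scargle spectral analysis of the
    unevenly sampled interbeat series with ULF/VLF/LF/HF band powers, two
    spectral bias corrections driven by an a-priori cohort spectrum, a 24-hour
    cosinor model of the circadian heart-rate rhythm, estimator validation
    statistics, cardiovascular-risk classifiers with baselines, and a synthetic
    24-hour beat-series generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
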