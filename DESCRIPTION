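Package: gaitevents
Title: Gait Event Detection for Exoskeleton-Assisted Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects heel-strike and toe-off events in treadmill walking
    trials from vertical ground reaction force and heel marker height.
    Per-signal LSTM sequence-to-sequence regressors predict Gaussian
    event-confidence curves which are fused by a signed-power weighting
    rule and decoded by constrained peak detection.  Includes the
    conventional body-weight-fraction GRF threshold baseline, a full
    event-timing error-metric suite (mean error, median absolute error,
    IQR, success and detection rates, extra-event counts), signal
    preprocessing (zero-phase Butterworth filtering, marker smoothing and
    upsampling), and a synthetic slow-walking gait simulator with clean,
    cross-plate and foot-drag strike conditions for fully reproducible
    benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
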