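Package: dyncouple
Title: Dynamic Coupling of EEG Oscillatory Power and fMRI Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the dynamic coupling between EEG
    oscillatory band power and fMRI functional connectivity measured
    simultaneously. Implements Gaussian tapered sliding-window dynamic
    functional connectivity, per-epoch multitaper band-power estimation
    with global-spectrum normalization, Fisher-Z coupling statistics with
    lag validation, and Post-Pre by Active-Sham double-contrast group
    tests with Benjamini-Hochberg correction across network hubs. A
    latent-state simulator generates ground-truth-known EEG and BOLD
    study datasets so the full pipeline can be calibrated and validated
    without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
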