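Package: eegdyn
Title: Nonlinear Dynamical Biomarkers from Infant EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for resting-state infant EEG: dyadic
    Daubechies wavelet band decomposition, nine nonlinear invariant
    measures per sensor and band (recurrence quantification statistics,
    sample entropy, detrended fluctuation analysis), support-vector-machine
    leave-one-out outcome classification with recursive feature
    elimination, severity estimation from decision-boundary distance with
    an uncertainty zone, permutation significance testing, and
    group-difference and developmental-trajectory summaries. Includes a
    synthetic-cohort generator (fractional Gaussian noise plus
    deterministic oscillatory components) so the full pipeline is testable
    without clinical recordings, and a minimal EDF reader/writer for
    fixtures.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
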