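Package: rtnse
Title: Real-Time Ensemble-Average Spectral Estimation for Fractionated Electrograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline (block) and real-time (per-sample streaming) implementations
    of an ensemble-average power spectral estimator for periodicity analysis of
    biomedical time series, developed for dominant-frequency analysis of
    fractionated atrial electrograms in the 3-12 Hz electrophysiologic band.
    The streaming form maintains, for every candidate period, a ring buffer of
    moving-average ensemble means and an incrementally updated sum of squares,
    yielding one full power spectrum per input sample. Includes spectral
    parameter extraction (dominant amplitude and frequency, mean and standard
    deviation of the normalized spectral profile), a sliding-window radix-2 DFT
    baseline with spectral-resolution calculators, a synthetic
    fractionated-electrogram generator with known ground truth, multichannel
    streaming orchestration, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
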