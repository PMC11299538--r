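Package: rpspect
Title: Recovery-Period Correction of Spike-Train Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detection of oscillations in single-unit spike trains whose power
    spectra are distorted by the post-spike recovery period. Provides a
    discrete-time inhomogeneous Poisson simulator with an exponentially rising
    recovery period, Welch spectral estimation of binary 1 kHz spike trains
    with a high-frequency-derived one-sided significance test, the
    inter-spike-interval shuffling correction (for unbroken trains and for
    trial-windowed data), estimation of the recovery-period duration from the
    ISI distribution by deviance-difference model comparison, a bounded
    last-spike Poisson point-process model whose raw residuals yield
    distortion-corrected spectra, hit/false-alarm labeling with partial-ROC
    benchmarking of correction methods, and Gaussian-mixture screening of
    trial windows for firing-rate homogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
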