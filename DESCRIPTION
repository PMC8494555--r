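Package: ceusflate
Title: Lossless Compression and Time-Intensity-Curve Quantification for
    Contrast-Enhanced Ultrasound Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lossless compression of one-dimensional sampled
    ultrasound signals and for quantitative analysis of contrast-enhanced
    ultrasound (CEUS) time-intensity curves (TICs). Provides from-scratch
    run-length, canonical Huffman, and raw DEFLATE (RFC 1951) codecs with a
    platform-aware algorithm-selection policy; signal preprocessing
    (burr smoothing, difference transform, Shannon entropy); gamma-variate
    bolus simulators with closed-form parameter oracles; nonparametric TIC
    indicator extraction (TTP, AUC, wash-in gradient, rise time, mean
    transit time, peak intensity, chord slopes); and cohort-level group
    comparisons, diagnostic test metrics, and power simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
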