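Package: cossvep
Title: Collaborative SSVEP Brain-Computer Interface Classification with
    Feature Fusion and Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for centralized collaborative steady-state visually
    evoked potential (SSVEP) brain-computer interfaces. Provides a seeded
    multi-subject SSVEP signal simulator (harmonic responses over
    pink-plus-white background noise), band-limited FFT magnitude-spectrum
    feature extraction with per-channel min-max normalization, three
    multi-subject feature-fusion operators (parallel channel stacking,
    serial frequency concatenation, and element-wise averaging), compact
    fusion-specific convolutional network classifiers with a deterministic
    seeded training engine, a two-stage transfer-learning protocol
    (pretraining followed by shallow-layer freezing and fine-tuning), and
    an evaluation workbench with stratified k-fold cross-validation,
    time-window sweeps, and information transfer rate reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
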