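Package: reegnet
Title: Residual Convolutional Networks for Cross-Subject EEG Motor Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains deep residual convolutional networks on raw multichannel
    EEG to decode motor-execution state (rest, left fist, right fist) across
    subjects, and explains the fitted classifier with gradient-weighted class
    activation mapping (Grad-CAM). Provides the block system (temporal,
    spatial, depthwise-separable convolutions with identity shortcuts), SGD
    training with cosine-annealed learning rate and max-norm constraints,
    per-trial normalization with two-scale noise augmentation,
    subject-disjoint cross-validation, Welch tests with Benjamini-Hochberg
    false-discovery-rate control for model comparison and channel-level
    attribution statistics, a synthetic EEG generator with planted
    band-limited class effects for end-to-end validation, an EDF+ reader for
    annotated recordings, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
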