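Package: wristfall
Title: Fall Detection from Wrist-Worn Accelerometers with LSTM Transfer
    Learning
Version: 0.1.0
Authors@R:
    person("wristfall", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects falls in tri-axial wrist accelerometer streams with a
    small LSTM classifier. Recordings are cut into overlapping fixed-size
    data blocks, per-block fall probabilities are smoothed with a trailing
    median window and thresholded. A layer-freezing transfer-learning
    protocol adapts a model trained on a large source device dataset to a
    small target dataset, possibly recorded at a different sampling rate,
    and synchronized left/right wrist models can be fused into an ensemble.
    Includes device profiles for heterogeneous watches, person-aware
    train/test splitting, leave-one-person-out cross-validation,
    precision-recall evaluation, a synthetic fall/ADL signal generator for
    fully reproducible experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
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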