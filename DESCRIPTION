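Package: angioflow
Title: Velocity Estimation from Projective Contrast Images with
    Optical Flow and Machine-Learning Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end framework for estimating blood-flow-like
    velocity fields from angiography-style projection images.  It
    simulates dye perfusion in a square duct by advecting a passive
    scalar through an analytic laminar flow field, renders 8-bit
    grayscale projection images via the discretized Beer-Lambert law,
    estimates per-pixel velocity with a physics-based optical flow
    method extended with divergence and diffusion terms, and corrects
    the optical-flow estimate with multi-output regression models
    (LASSO, multilayer perceptron, 1-D convolutional network, and LSTM)
    trained against the simulated ground truth.  Includes repeated
    k-fold cross-validation, per-station percentage-error profiles, and
    a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
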