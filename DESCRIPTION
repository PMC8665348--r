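Package: refocus
Title: Sorting and Reconstruction of Defocused Phase-Contrast Cell Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deep-learning workflow for high-throughput phase-contrast cell
    imaging: a small convolutional classifier (SDCNN) sorts focused from
    defocused frames, and a residual U-Net with instance normalization
    (ResUNet) reconstructs the defocused ones at subcellular detail. Includes
    a synthetic phase-contrast scene and defocus simulator for fully
    self-contained training and evaluation, SSIM/L1/combinatory loss
    functions, five-fold cross-validation and transfer-learning protocols, a
    Richardson-Lucy deconvolution baseline with per-channel grid search, and
    an end-to-end command-line pipeline that sorts a directory of images and
    reconstructs the flagged ones. All network layers are implemented in
    compiled code; no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
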