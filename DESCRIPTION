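Package: hsipath
Title: Hyperspectral Histopathology Classification and Margin Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for microscopic hyperspectral imaging of H&E-stained
    histology slides: transmittance calibration against white-reference and
    dark-current frames, patch tiling and anti-aliased resizing, a
    hyperspectral RandAugment data-augmentation policy (including NMF-based
    stain augmentation in optical-density space), a spectral-spatial
    factorized-attention transformer classifier trained with SGD and
    patient-stratified splits, whole-slide tumor-margin assembly scored with
    the Jaccard index and the Hausdorff distance in millimetres, and
    attention-rollout visualization. Ships a seed-reproducible synthetic
    generator of H&E-like hypercubes so the full pipeline runs without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    EBImage,
    rhdf5,
    png,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
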