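Package: dissolvis
Title: Simulation, Multimodal CNN Modelling and Grad-CAM Explanation of
    Surface Dissolution Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predictive-interpretive modelling of tablet surface
    dissolution imaging. Includes a physics-inspired simulator of
    dual-wavelength (280 nm API / 520 nm structural) absorbance image
    sequences with known dissolved-fraction labels and ground-truth saliency
    masks; dataset assembly utilities (calibration fits, cumulative release
    correction for replaced sampling volume, seeded train/test splits,
    one-hot condition encoding, time-matrix construction); a from-scratch
    multimodal convolutional regression network (dual image branches, time
    branch, composition branch, Adam/MSE) with an ablation ladder and a
    linear baseline; Grad-CAM saliency for the scalar release prediction
    with an occlusion oracle and edge/core localization statistics; and a
    one-command reproduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
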