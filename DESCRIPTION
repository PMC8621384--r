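Package: vesselx
Title: Retinal Vessel Enhancement and Segmentation with Jerman Filtering
    and Curvelet-Domain Contrast Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of retinal blood vessels in fundus
    photographs. Implements the multiscale 2D Jerman vesselness filter
    (Hessian eigenvalue ratio with cut-off regularization), a fast discrete
    curvelet transform via wrapping with Meyer-type radial and angular
    windows, curvelet-coefficient enhancement (core-level suppression and
    fine-level amplification), local mean-C adaptive thresholding, and
    morphological cleanup. Includes seeded synthetic phantom generators
    (tubes and branching vessel trees with exact ground truth), pixel-level
    evaluation metrics (sensitivity, specificity, accuracy, precision), a
    dataset-level evaluation harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    grDevices,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    dplyr,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
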