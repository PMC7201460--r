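Package: hemaseg
Title: Semantic Segmentation of Whole-Slide Blood Smear Images
Version: 0.1.0
Authors@R: person("hemaseg", "maintainers", email = "hemaseg@example.org",
    role = c("aut", "cre"))
Description: Tools for pixel-level semantic segmentation of whole-slide
    blood smear microscopy images into red blood cells, white blood cells
    and platelets. Provides a parametric synthetic smear generator with
    exact ground-truth masks, mask preprocessing and label fusing with the
    standard pixel-ID convention (background 0, RBC 1, WBC 2, platelet 3),
    a configurable convolutional encoder-decoder segmentation network with
    a VGG-style encoder trained by minibatch stochastic gradient descent,
    an evaluation suite (per-class accuracy, intersection-over-union,
    boundary-F score, global and mean summaries) and classwise pixel
    counting, all orchestrated by a reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
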