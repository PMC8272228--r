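Package: brachytherm
Title: Thermal-Imaging Analysis of Muscle Activation in the Upper Arm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for locating and differentiating activated upper-arm
    (brachium) muscles from infrared thermal image sequences recorded during
    isolated resistance training. Covers training-protocol timing arithmetic,
    a synthetic thermal-session simulator with piecewise-linear skin
    temperature dynamics, frame and session input/output, Otsu-based arm
    segmentation, 60 x 20 grid heat maps with difference heat maps and
    muscle-region statistics, temperature elevation rates, a Kruskal-Wallis
    training-order test, and a small convolutional network that classifies
    difference heat maps into biceps, triceps, deltoid or vague activation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
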