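Package: cropseg
Title: Central Roundish Object Segmentation and Time-Lapse Fruit Growth
    Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully convolutional encoder-decoder networks for segmenting the
    single roundish object at the centre of an image (for example a target
    fruit in fixed-camera orchard photographs), trained with a symmetrized
    soft dice loss and evaluated by intersection-over-union.  Includes
    dihedral (D4) test-time augmentation, a robust multi-scale median area
    measurement, centre-of-mass tracking over time-ordered image series,
    daytime filtering, coefficient-of-variation outlier replacement and
    polynomial growth-curve fitting, together with a synthetic scene and
    growth-series generator so that every stage can be trained and tested
    at desk scale.  The convolutional kernels (forward and backward) are
    implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    mgcv,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
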