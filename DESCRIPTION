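Package: dsaddle
Title: Saddle-Point Feature Detection and Retinal Fundus Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feature-based registration of retinal fundus image pairs built
    around the D-Saddle detector: saddle-point candidates are screened by
    inner/outer ring intensity pattern tests on a four-octave multiresolution
    difference-of-Gaussian pyramid, described with histogram-of-oriented-
    gradients descriptors, matched by a nearest-neighbour ratio test, and
    aligned with MSAC-robust similarity, affine or second-order polynomial
    transformations. Includes target registration error evaluation against
    landmark ground truth, image-quality metrics (MSE, SSIM, peak deviation
    nonuniformity), and a synthetic fundus phantom generator that produces
    image pairs with known transformations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
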