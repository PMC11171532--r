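Package: mammosub
Title: Bilateral Mammogram Subtraction with Unsupervised Nonrigid Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for subtraction processing of bilateral mediolateral-oblique
    (MLO) mammograms to support comparative interpretation. The horizontally
    flipped left-breast image is registered onto the right-breast image with a
    convolutional deformation-field network (a 2-D VoxelMorph-style U-Net with
    a spatial-transformer warp), trained without supervision on a masked
    mean-squared-error plus displacement-smoothness loss. Includes skin-line
    based breast segmentation and 512x512 preprocessing, sum-of-absolute-
    differences (SAD) evaluation with quartile subgroup analysis, a synthetic
    bilateral breast-phantom generator with ground-truth deformation fields
    for end-to-end testing, and a reproducible simulate/preprocess/train/
    evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
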