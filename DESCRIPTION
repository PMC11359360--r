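Package: cphnet
Title: Stem Segmentation of Seedling Point Clouds with Channel and
    Position Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semantic segmentation of 3D plant point clouds into stem and
    non-stem points using a hierarchical set-abstraction network (CPHNet)
    with channel-residual attention perceptrons (CRA-MLP), position-enhanced
    self-attention (PESA), and a hybrid cross-entropy plus Dice loss.
    Includes readers and writers for labelled PLY, PCD and XYZ point clouds,
    statistical outlier filtering, rotation/jitter/noise augmentation,
    grouped train/test and k-fold splitting, a parametric generator of
    labelled seedling scenes with soil, pot, wall and outlier clutter, a
    seeded training loop with cosine learning-rate decay, and class-averaged
    IoU, precision, recall and F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
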