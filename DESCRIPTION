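Package: circlenet
Title: Circle-Based Keypoint Detection of Signet Ring Cells in Histology Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anchor-free detection of signet ring cells with circular bounding
    boxes. Ground-truth circles are encoded as per-class Gaussian centre
    heatmaps with sub-cell offset and radius regression targets; a modified
    ResNet-34 backbone with convolutional block attention (CBAM), an
    upsampling decoder and three prediction heads is trained with a
    penalty-reduced focal loss plus L1 regression losses, and decoded
    detections are scored with exact circle-IoU localisation metrics (per-class
    AP, mAP, mean matched IoU) and image-level classification metrics. Includes
    joint image/annotation augmentation, VIA-style JSON and CSV annotation IO,
    a seeded synthetic tile generator with exact ground truth, and a
    command-line pipeline (generate, augment, train, detect, evaluate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    data.table,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
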