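Package: pigweigh
Title: Pig Body Weight Estimation from Top-Down 3D Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the live body weight of grow-finish pigs from top-down
    3D point clouds captured by a ceiling-mounted depth camera. Implements the
    full pipeline: reading and writing point clouds (PLY and CSV), the filter
    chain that isolates the animal surface from pen clutter (depth-band,
    polygon region-of-interest, Otsu colour segmentation, statistical outlier
    removal, random subsampling, automated head cropping), a 2.5D
    projected-volume linear baseline on a rasterized height grid, and a
    permutation-invariant point-set neural network regressor (PointNet-style
    shared multilayer perceptron with max pooling and an input transform
    network) trained with Adam, per-epoch jitter augmentation and early
    stopping. A synthetic pig-cloud generator with known geometry, weight
    labels and depth-sensor artifacts makes every stage testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
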