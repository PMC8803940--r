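Package: brainseg
Title: Two-Stage Convolutional Whole-Brain MRI Segmentation and Reliability Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for whole-brain segmentation of T1-weighted MR
    volumes: a convolutional regression network localizes the brain with a fixed-size
    bounding box, and a U-Net-style volumetric network segments overlapping subvolumes
    of the cropped block whose merged predictions are padded back to the full field of
    view with an Unknown label.  Ships a compact CPU 3D convolution engine, a labeled
    head-phantom generator with segmented k-space rigid-motion artifact simulation for
    graded image-quality tiers and repeated sessions, per-region segmentation
    similarity metrics (Dice, Jaccard, Hausdorff distance, relative volumetric
    difference), head-motion and test-retest pairing designs, and nonparametric method
    comparison with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
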