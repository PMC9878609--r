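Package: rsnmap
Title: Voxelwise Resting-State Network Mapping with a 3D Dense-Residual
    Convolutional Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps resting-state networks (RSNs) voxel by voxel from
    resting-state fMRI. Seed-based two-channel similarity volumes (Pearson
    correlation and Euclidean distance of normalized BOLD series) are
    classified by a 3D densely connected convolutional network with nested
    residual units and deep supervision, yielding per-voxel softmax RSN
    membership probabilities. Includes group statistics (mean, SD, mean/SD),
    winner-take-all segmentation, network summary measures, a 3D multiscale
    structural similarity index, frame-truncation and pink-noise robustness
    protocols, softmax- and time-series-derived connectivity matrices, and a
    synthetic phantom generator that emulates preprocessed RS-fMRI with
    planted network covariance so the whole pipeline runs end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
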