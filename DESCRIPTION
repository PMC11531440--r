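Package: lcntools
Title: Quantification of the Osteocyte Lacunocanalicular Network from 3D
    Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to extract and quantify the osteocyte lacunocanalicular
    network (LCN) of bone from 3D fluorescence image stacks. Provides a
    ground-truthed synthetic phantom generator (ellipsoidal lacunae,
    tubular canaliculi, tree-like branching with an exponential degree
    tail, ordered and unordered regions, confocal-like blur and noise), a
    five-step image-to-network pipeline (difference-of-Gaussians adaptive
    binarization, size-based lacuna/canaliculus segmentation, 3D
    topology-preserving skeletonization, smoothing-spline branch
    smoothing, translation into a spatial graph), network and lacunar
    morphometry (canalicular density, node number and degree in cubic
    subvolumes, ellipsoid shape descriptors, cumulative degree
    distributions with exponential-tail fits, regressions, smoothed
    histograms, variability decomposition, group tests), region-wise
    statistics over ordered/unordered masks, and quantitative
    backscattered electron imaging (qBEI) gray-level to calcium-content
    calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
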