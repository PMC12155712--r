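Package: octfuse
Title: Motion-Corrected Multi-Volume OCT Fusion and Longitudinal
    Tracking of Subretinal Drusenoid Deposits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and processing of multi-volume orthogonal raster
    optical coherence tomography (OCT) acquisitions of the macula.
    Provides a synthetic retina and acquisition simulator (layered
    phantoms, drift and saccade eye motion, illumination bias, speckle,
    blinks), blink removal by relative thresholding, joint per-A-scan 3D
    eye-motion estimation from orthogonally scanned volumes, smooth
    illumination gain correction, dynamic-programming segmentation of
    Bruch's membrane, flattening and multi-volume fusion, averaged en
    face slab projection, and longitudinal tracking of dot-form
    subretinal drusenoid deposits with stable/regressed/fused/new
    classification, quadrant assignment and summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    EBImage,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
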