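Package: irai
Title: Sensitivity-Compensated Quantitative Ionizing Radiation Acoustic Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for ionizing radiation
    acoustic imaging (iRAI) with a 2D matrix array transducer. Simulates the
    transducer's volumetric detection sensitivity by a dynamic-focusing sweep
    and by a virtual point-source protocol, forward-models radiation-induced
    acoustic signals from voxelized dose distributions by retarded-potential
    superposition in a homogeneous medium, reconstructs 3D images by
    delay-and-sum beamforming with envelope detection, compensates voxel-wise
    by the reciprocal of the normalized sensitivity map, and quantifies
    agreement with a planned dose via dose-volume histograms, global gamma
    index analysis, structural similarity, isodose contours, and region-mean
    amplitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
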