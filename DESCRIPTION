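Package: moirepose
Title: Moire Fiducial Marker Optical Head-Pose Tracking for MRI Motion Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A test platform for optical head-pose tracking in the MRI
    environment. Implements a moire-enhanced fiducial marker model and its
    frame-analysis pipeline (ArUco-style anchor detection, homography
    rectification, moire profile extraction and sinusoid phase fitting),
    6-DOF pose estimation combining planar perspective-n-point, stereo
    direct-linear-transform triangulation and moire phase angles, camera
    intrinsic/extrinsic calibration with a 50-placement protocol generator,
    SVD rigid-body cross-calibration between camera and scanner coordinate
    frames, a noisy-sinusoid physiological motion simulator, a synthetic
    scene renderer (marker views and a procedural head proxy) so that every
    stage is testable without hardware, and a compact convolutional network
    that regresses inter-frame 6-DOF pose deltas from paired camera views.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
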