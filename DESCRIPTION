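Package: depthreg
Title: Markerless Patient Registration with Tracked Depth Cameras
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation framework for depth-camera-based markerless patient
    registration in image-guided surgery. Implements rigid-body transform
    algebra, pinhole camera calibration (homography-based intrinsics recovery
    with nonlinear refinement), hand-eye co-registration of a tracked camera
    against a tracked checkerboard, RANSAC-initialised point-to-point ICP
    surface registration, and fiducial/target registration error (FRE/TRE)
    evaluation with an overlap-based exclusion gate. A built-in simulator
    generates a parametric phantom head, tracked poses with jitter,
    checkerboard observations and depth captures under per-technology noise
    presets, so the full pipeline is verifiable against ground truth without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
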