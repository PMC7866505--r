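Package: vbtrack
Title: Video-Based Barbell Velocity Tracking with Autocalibrated Plane Homographies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a video-based instrument for unattended measurement of
    barbell displacement, velocity, force, and power on a multipower (Smith)
    machine. A two-plane homography procedure autocalibrates the camera from
    four warning-tape reference corners on the structural pillars and transfers
    the calibration to the parallel barbell (guide) plane; colored barbell
    marks are detected per frame by circular-hue segmentation with top-hat
    bandpass morphology inside RANSAC-restricted search strips; concentric-phase
    kinematics (range, mean and peak velocity, force, power) are derived from
    the metric height series; and instrument-agreement statistics (ICC(2,1),
    Cronbach's alpha, Bland-Altman limits, SWC/SEM usefulness, Pearson r with
    SEE) validate paired measurements. A synthetic scene renderer produces
    fully ground-truthed test sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
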