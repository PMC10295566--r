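Package: posegait
Title: Markerless Gait Assessment from 3D Pose Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for markerless clinical gait analysis from monocular-camera
    3D pose keypoints with per-joint visibility scores. Converts keypoints into
    sagittal-plane knee and hip angle signals, imputes and smooths them with a
    constant-acceleration Kalman filter whose missing-measurement substitution is
    gated on visibility (prior- or posterior-substitution variants), denoises with
    a discrete-Fourier-transform component-selection filter under a least-RMSE
    strategy, extracts discrete gait parameters (joint flexion range of motion and
    striding speed), builds gender-stratified PCA feature models scored with the
    Hotelling T-squared distance, and evaluates agreement against gold-standard
    signals (range-normalised percentage error, length-normalised dynamic time
    warping, Bland-Altman limits of agreement, correlation and regression,
    principal-component cosine similarity). Includes synthetic generators - a
    cosine-composed gait-signal simulator and a kinematic stick walker - so the
    whole pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
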