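Package: mousegaze
Title: Gaze Reconstruction and Saccade Analysis for Head-Mounted Eye
    Tracking in Freely Moving Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for reconstructing gaze in freely moving mice
    during prey capture from head-mounted eye cameras, overhead video
    landmarks, and an inertial measurement unit. Fits pupil ellipses and
    calibrates eye cameras from pupil ellipticity, estimates head pose by
    rigid landmark fitting, places all channels on a common 60 Hz
    timebase, detects approach epochs from speed, azimuth and closing
    rate, reconstructs gaze as head plus eye angle, segments saccades and
    fixations at a gaze-velocity threshold, and computes lagged
    cross-correlations, event-triggered averages and stabilization
    statistics. Includes a synthetic-session generator with ground truth
    so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
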