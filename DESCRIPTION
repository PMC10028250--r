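Package: gaitscreen
Title: Automated Locomotor Screening from Markerless Pose Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for diagnostic screening of quadruped
    locomotion from 2-D pose-estimation landmark trajectories. Extracts
    quality-filtered stride cycles from DeepLabCut-style landmark tables,
    computes joint-angle profiles and dimensionless spatiotemporal gait
    variables, separates dynamic posture from intra-limb coordination via
    Fourier Coefficient Affine Superimposition (FCAS), and trains a
    probabilistic linear model that infers subject characteristics (mass,
    size, age) from kinematics. Out-of-sample posterior-predictive inference
    flags individuals whose age is consistently underestimated, a screening
    signal for delayed locomotor development. Includes a fully deterministic
    synthetic cohort and planar walker generator so every stage is testable
    without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
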