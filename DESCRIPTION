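Package: graspflow
Title: Analysis Pipeline for Delayed-Grasping Electrophysiology Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing delayed-grasping experiments in which grasps
    are instructed either visually or tactually: a synthetic session generator
    with known ground truth (trial scheduler, inhomogeneous-Poisson spike
    trains, joint-angle hand kinematics, optional broadband signals),
    spike-band preprocessing with PCA common-artifact cancellation and
    threshold spike detection, behavioral reaction- and movement-time
    analysis, settled-grasp posture features with grip-similarity
    dendrograms, sliding-window two-way ANOVA tuning time courses, and
    trial-balanced leave-one-out linear discriminant decoding of object and
    sensory modality with confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
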