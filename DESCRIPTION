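Package: gaitfrail
Title: Smartphone Accelerometry Gait and Posture Features for Preoperative
    Frailty Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts gait and postural-stability features from tri-axial
    accelerometer recordings made with a pelvis-worn smartphone (zero-phase
    Butterworth filtering, moving-window-variance walk detection, 5-m gait
    speed, inter-step time, per-axis RMS, approximate entropy and sway
    dispersion metrics), classifies frailty by gait speed, and evaluates a
    published linear adverse-postoperative-outcome score for older adults
    undergoing cardiac surgery. Includes a seeded synthetic-cohort generator
    emulating frail and non-frail recordings, model refitting with Mallows' Cp
    and variance-inflation diagnostics, group comparison, optimal cut-point
    analysis, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    car
Config/testthat/edition: 3
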