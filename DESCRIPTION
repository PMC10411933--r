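Package: aimkin
Title: Kinematic Analysis of FPS-Style Aiming Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing centre-out aiming movements of
    the kind made in first-person-shooter (FPS) games and aim trainers. Provides
    the task logic for a staircased shooting task in two equated visuomotor
    contexts (cursor translation vs. camera pan/tilt), a synthetic movement
    generator with minimum-jerk primary movements, signal-dependent noise and
    iterative corrective submovements, segmentation of cursor trajectories into
    reaction, primary-movement, correction and click-dwell phases, a suite of
    spatial and temporal performance metrics (radial extent, peak speed, hand
    angle, linearity index, endpoint error ellipses, Fitts-law effective index
    of difficulty), and participant-level data-quality screening rules.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
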