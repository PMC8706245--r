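Package: jumpkin
Title: Biomechanics of Children's Vertical Jumping from Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for marker-based motion capture and force-plate
    recordings of preschool children's countermovement vertical jumps. Provides
    zero-phase Butterworth filtering and kinematic/kinetic synchronization,
    five-phase jump segmentation (compression, pushing, flight, landing,
    standing), developmental-stage classification, sagittal joint kinematics and
    spatiotemporal metrics, planar link-segment inverse dynamics with redundant
    muscle-recruitment optimization (polynomial and min/max criteria), cohort
    statistics (two-way ANOVA with partial eta-squared, LSD post-hoc, stepwise
    regression with VIF and Durbin-Watson diagnostics), and a synthetic-jump
    generator so every stage is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
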