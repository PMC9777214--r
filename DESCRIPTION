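Package: armkin
Title: Closed-Form Six Degree-of-Freedom Arm Kinematics and Shoulder
    Range-of-Motion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Denavit-Hartenberg forward kinematics of the
    clavicle-shoulder-elbow-wrist chain, a geometric closed-form inverse
    kinematics solution that reconstructs the elbow and shoulder centres
    from a measured end-effector pose with anatomically motivated branch
    selection, and an end-to-end motion-capture pipeline that turns
    labelled marker trajectories into joint-angle time series, per-joint
    range of motion (ROM), composite shoulder ROM, and sex-stratified
    cohort statistics.  A synthetic-motion generator produces ground-truth
    joint profiles and marker clouds through the forward model so every
    pipeline stage is testable without captured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
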