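Package: scedrink
Title: Single-Case A-B-A Statistics and Drinking-Task Kinematics for
    Upper-Limb Stroke Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-case experimental designs (SCED)
    in upper-limb stroke rehabilitation. Computes Kendall-S pair counts,
    phase-nonoverlap Tau and baseline-trend-corrected Tau-U effect sizes
    with permutation or normal-approximation p-values, and reports change
    between baseline and post-intervention phases against minimal
    clinically important difference (MCID) thresholds. Extracts movement
    time, number of movement units (smoothness) and compensatory trunk
    displacement from 3D motion-capture marker trajectories of the
    standardized drinking task. Includes a synthetic-data module that
    generates minimum-jerk drinking trials and A-B-A assessment series
    with known ground truth, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
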