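Package: splitbelt
Title: Split-Belt Treadmill Locomotor Adaptation Analysis for Post-Stroke Gait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: A stride-by-stride analysis pipeline for split-belt treadmill
    adaptation studies of hemiparetic gait: heel-strike detection from
    ground-reaction forces, step length asymmetry and leading/trailing leg
    orientations from marker kinematics, body-weight normalised peak
    propulsion forces, epoch outcome measures (Baseline, Late Adaptation,
    After-Effects, change scores), and the accompanying statistical battery
    (paired and one-sample t-tests with paired Cohen's d, repeated-measures
    ANOVA with eta squared, Monte Carlo Lilliefors normality, and
    regression through the origin). Includes a synthetic trial generator
    that emits raw marker and force-plate signals with known stride-level
    truth so the whole pipeline is testable without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
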