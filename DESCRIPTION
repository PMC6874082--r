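Package: beastsim
Title: Simulation and Inference for a Social-Information Estimation Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses an incentivised numerosity-estimation
    experiment (the Berlin Estimate AdjuStment Task, BEAST) in which
    participants revise an estimate after seeing controlled social
    information from a peer or an adult source. Provides the task engine
    (stimulus schedule, target-value rule, nearest-bank selection,
    payoffs), a pre-recorded estimate bank, a synthetic adolescent cohort
    responding through a stay/copy/compromise heuristic mixture, the
    adjustment statistic s = (E2 - E1)/(X - E1) with validity filtering
    and heuristic classification, paired tests and nested mixed-effects
    models ('lme4'), and a parameter-recovery and calibration harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
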