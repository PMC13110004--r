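Package: mrdsim
Title: Joint Simulation of Longitudinal Minimal Residual Disease
    Trajectories and Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic longitudinal minimal-residual-disease (MRD)
    datasets jointly with time-to-event outcomes. MRD trajectories follow a
    three-phase piecewise model (exponential decay to a plateau, optional
    exponential relapse); event times are sampled from a Cox hazard driven by
    the trajectory's current value, slope, and cumulative burden. Includes
    subgroup/cohort configuration, assessment schedules with jitter and
    missingness, limit-of-detection flagging, Kaplan-Meier and log-rank
    summaries, Monte-Carlo power analysis, and a versioned JSON/CSV dataset
    format with ground-truth export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    optparse,
    rlang,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
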