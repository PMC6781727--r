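Package: hftraj
Title: Dynamic 30-Day Readmission Risk Trajectories for Heart Failure
    Hospitalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-stage dynamic prediction pipeline for 30-day hospital
    readmission risk over the course of a heart-failure hospitalization.
    Engineered time-series characteristics of vitals and laboratory
    results (counts, extremes, normalized extremum indices, recent
    means) feed an encounter-level logistic regression with backward
    elimination; its predictions on time-truncated data serve as
    counterfactual daily readmission risks, which a beta regression
    re-predicts from the same truncated features. Per-encounter risk
    trajectories over seven in-stay milestones are clustered with
    K-means and the resulting risk groups are characterized with
    Kruskal-Wallis discriminant screening and temporal profiles. A
    synthetic electronic-health-record cohort generator with planted
    risk-trajectory archetypes makes the whole pipeline runnable and
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
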