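Package: adhema
Title: Inhaler Adherence and Momentary-Assessment Analytics for
    Longitudinal Asthma Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing smartphone-based asthma monitoring data:
    ingestion and validation of Bluetooth inhaler actuation streams,
    daily ecological momentary assessment (EMA) self-reports, and
    per-participant controller regimens; device/manual event
    deduplication; capped 12-hour-window adherence metrics; rule-based
    asthma-symptom-day and new-symptom-episode detection; data-acquisition
    summaries; linear mixed models with participant random intercepts
    relating daily symptoms and mood to adherence, including a
    missing-report imputation sensitivity analysis; and a synthetic
    longitudinal cohort simulator with known ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
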