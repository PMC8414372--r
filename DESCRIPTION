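Package: alarmeval
Title: Evaluation of Clinical Early-Warning Alarm Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scoring irregular vital-sign time series with the
    Modified Early Warning Score (MEWS) and for evaluating the resulting
    threshold alarms as a clinical prediction index. Implements three score
    sampling variants (event-driven, interval median, interval worst-case)
    with last-observation-carried-forward imputation, alarm classification
    against a prediction horizon and lead time, patient-level confusion
    metrics with ROC/PRC threshold sweeps, time-dependent sensitivity,
    bootstrapped false-positive ratios, the work-up-to-detection ratio,
    alarm-burden rates and proportions, and alarm time profiles. A synthetic
    cohort generator with a plantable pre-event deterioration signal supports
    end-to-end testing without access to protected health records.
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
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
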