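Package: chronofeed
Title: Circadian Behavior and Physiology Analysis for Time-Restricted
    Feeding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for circadian intervention studies in rodents:
    chi-square periodogram rhythm power, activity bout segmentation, activity
    onset variability, immobility-defined sleep scoring, time-domain heart
    rate variability (NN/SDNN), housekeeping geometric-mean normalization of
    expression count panels, and the accompanying group-statistics layer
    (summary-based and raw two-sample t tests, two-way repeated-measures
    ANOVA, Holm-Sidak step-down adjustment, Pearson correlation,
    normality/equal-variance screens). Includes a synthetic cohort generator
    emulating the data structure of a time-restricted-feeding study so every
    analysis stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
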