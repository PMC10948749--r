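Package: cgmetrics
Title: Glycemic Variability Indices, Cohort Simulation and Analysis for
    Continuous Glucose Monitoring Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-cohort continuous glucose monitoring (CGM) studies:
    reading, validating and resampling timestamped glucose traces; the standard
    suite of glycemic-variability indices (time in range, MAGE, J-index,
    LBGI/HBGI via the blood-glucose risk transform, ADRR, MODD, CONGA); a
    transparent weighted composite metabolic score; a calibrated synthetic-data
    generator for healthy and pre-diabetic cohorts with correlated biomarker and
    activity panels; and the cohort statistics stage (outlier rules,
    normality-gated correlation, two-way group-by-day comparison, ANCOVA, ROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    emmeans,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
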