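Package: shiftsub
Title: Time-Use Extraction and Isotemporal Substitution Models for
    Night-Shift Worker Cohorts
Version: 0.1.0
Authors@R:
    person("shiftsub", "authors", email = "maintainer@shiftsub.example",
           role = c("aut", "cre"))
Description: Classifies epoch-level triaxial accelerometer records into
    sedentary behaviour (SB), light physical activity (LPA),
    moderate-to-vigorous physical activity (MVPA) and main sleep using
    METs cut-points; segments recordings into 24-hour workday and
    leisure-day windows from a work roster; aggregates per-day-type time
    use with minimum-wear-day rules and an exclusion cascade; and
    estimates associations between time reallocation and cardiovascular
    disease risk factors with single-factor and isotemporal substitution
    regression models (standardized coefficients, Wald confidence
    intervals, variance inflation factors). A synthetic-cohort generator
    with known ground truth (shift calendars, epoch streams, outcomes
    with planted substitution effects) makes every pipeline stage
    testable without access to raw study data. A command-line entry
    point orchestrates simulate, extract, fit and report stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
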