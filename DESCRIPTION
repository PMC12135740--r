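Package: equitach
Title: Rhythm Analysis of Exercising Equine Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Equitach", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and classify premature complexes in RR-interval
    tachograms recorded during equine exercise, compute per-workout arrhythmia
    burden and heart-rate metrics, and run cohort-level descriptive and
    mixed-effects association analyses. Includes a synthetic exercise-ECG
    cohort simulator with ground-truth event ledgers so that every stage of
    the pipeline can be validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    lme4,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
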