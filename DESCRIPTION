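Package: ardsscreen
Title: Retrospective ARDS Case-Finding with Persistence-Based Physiologic Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective identification of acute respiratory
    distress syndrome (ARDS) cohorts in ICU electronic health record
    extracts. Implements Berlin physiologic screening (PaO2/FiO2 < 300 mm Hg
    contemporaneous with PEEP >= 5 cm H2O) with configurable persistence
    windows, including the 72-hour rule and its 48-hour-with-death-on-day-3
    variant; radiology-report keyword rule-sets with negation masking and
    ICD code-set matching as enrichment signals; a diagnostic-accuracy layer
    (confusion matrices, Wilson and Clopper-Pearson intervals, Cohen's
    kappa, finite-population margins of error, positive-predictive-value
    gradients, odds ratios); and a calibrated synthetic ICU cohort generator
    so the full pipeline is testable without credentialed data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
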