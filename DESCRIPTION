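Package: gesticulate
Title: Gesture Laterality from Bilateral Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts bilateral wrist accelerometer recordings made during
    speech tasks into gesture laterality metrics (movements per minute per
    arm and the median magnitude ratio, MMR), scores prosthesis daily-use
    and embodiment questionnaires, and runs the associated statistical
    battery (Spearman correlation, exact Mann-Whitney U, one-sample and
    paired t tests with JZS Bayes factors, 2x2 mixed ANOVA, Type III
    ANCOVA). Includes simulators for bimanual gesture accelerometry with
    known ground truth and for cohort tables with controlled effect sizes
    and rank correlations, so the full pipeline is testable without any
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    MASS,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
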