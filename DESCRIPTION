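Package: meldkit
Title: MELD-Family Prognostic Scores and Waiting-List Mortality Validation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes nine end-stage-liver-disease prognostic scores (MELD,
    MESO index, MELD-Na, UKELD, iMELD, refitMELD, refitMELD-Na, upMELD and
    PELD) with their published variable-handling rules (floors, caps,
    dialysis substitutions, rounding), and provides the machinery to
    validate them against 90-day waiting-list mortality: a seeded synthetic
    waiting-list cohort generator, ROC/AUROC analysis with DeLong and
    bootstrap confidence intervals and sub-cohort matrices, univariable
    screening with collinearity resolution and forward likelihood-ratio
    logistic regression, and the Jacob 20-point quality-assessment
    instrument for prognostic-model studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
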