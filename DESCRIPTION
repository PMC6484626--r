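Package: patchcv
Title: Grouped Cross-Validation and Multi-Expert Agreement Evaluation for
    Histopathology Patch Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation methodology for patch-based histopathology
    classifiers: grouped k-fold cross-validation at patient, core, or patch
    level with leakage auditing; majority-vote ground truth aggregated from
    multiple imperfect annotators; per-fold accuracy, sensitivity, and
    specificity for cancer detection and low- vs high-grade Gleason
    classification; quadratic-weighted Cohen kappa agreement; and paired
    McNemar comparison of cross-validation schemes. A hierarchical synthetic
    cohort simulator (patient and core random effects, configurable annotator
    confusion and coverage) reproduces the patch-level leakage and
    single-expert-bias phenomena without any real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
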