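Package: rhinorules
Title: Rule-Based Diagnosis of Nasal Obstruction from Endoscopic Grading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A rule-based expert system that maps structured nasoendoscopic
    grading records (internal nasal valve, inferior turbinate, septal
    deviation, nasal polyps; pre- and post-decongestant; left and right) to
    multi-label nasal-obstruction diagnoses through a 32-row decision table.
    Includes multi-rater consensus aggregation (mode, then mean, then
    predefined fallback), one-vs-rest sensitivity and specificity with Wilson
    or Clopper-Pearson confidence intervals, paired method comparison by
    conditional logistic regression on matched pairs, power analysis for
    two-group proportion comparisons, Krippendorff's alpha with bootstrap
    confidence intervals, and a synthetic cohort generator with known gold
    diagnoses for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
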