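Package: mapleAC
Title: Priority-Level Assignment for Older Acute-Care Patients (MAPLe-AC)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Method for Assigning Priority Levels for Acute
    Care (MAPLe-AC), a five-level decision-support algorithm for older
    hospital patients built from interRAI-AC assessment items. Provides the
    embedded subscales (Cognitive Performance Scale, ADL hierarchy, ADL
    decline, behaviour-disturbance composite, geriatric screener, and the
    eight-category institutional-risk screener), a declarative and
    overridable encoding of the decision tree, a calibrated synthetic
    episode-cohort generator, and a validation harness with logistic
    regression (odds ratios, pseudo R-squared, c-statistics), ROC curves,
    Cox proportional-hazards models for days to death, and cohort
    cross-tabulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
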