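Package: scaleval
Title: Validation of Questionnaire Scales Against Categorical Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating continuous questionnaire scale scores
    (e.g. parent-report depression checklists scored from three-point
    Likert items) against categorical diagnoses from one or more
    informants. Implements the three preregistration-style case-control
    contrasts (sensitivity, specificity, strict specificity),
    prevalence-targeted control subsampling, tie-aware AUCROC with
    bootstrap inference against a fixed performance threshold,
    exploratory optimal-cutpoint and confusion-matrix reporting, and
    cross-informant agreement statistics. Because access to the large
    developmental cohorts this design targets is restricted, the package
    ships a latent-liability simulator that generates multi-informant,
    multi-disorder cohorts with configurable informant fidelity and
    comorbidity structure, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
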