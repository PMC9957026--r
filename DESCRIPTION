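Package: msitr
Title: Military Service Identification from Free-Text Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for detecting evidence of a patient's own
    military service in free-text clinical documents from secondary mental
    healthcare. Stage one is a keyword rule-based classifier over curated
    lexicons of military terms, confounder phrases (e.g. "Salvation Army")
    and relation words used to suppress mentions of other people's service.
    Stage two is a TF-IDF linear classifier with a rule-based postprocessing
    gate. Document decisions are aggregated to patient level and evaluated
    against self-reported ground truth with screening statistics (percent
    agreement, PPV, NPV, sensitivity, specificity, Youden index) and
    cohort-flow reporting. Includes a template-based synthetic corpus
    generator so the whole pipeline is testable without access to any
    electronic health record system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
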