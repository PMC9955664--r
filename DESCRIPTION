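Package: mohatree
Title: Rule-Based Determination and Validation of Mode of HIV Acquisition in Adolescents
Version: 0.1.0
Authors@R: person("Cohort", "Methods Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies the mode of HIV acquisition (vertical versus sexual)
    of adolescents living with HIV from longitudinal self-reported sexual,
    family, and treatment history. Implements a configurable logic-tree
    reference classifier, simple age-at-ART-initiation cutoff classifiers,
    and diagnostic validation of the cutoffs against the logic tree
    (sensitivity, specificity, predictive values, two-point ROC AUC).
    Includes a seeded synthetic-cohort generator with known true labels for
    end-to-end recovery experiments, CSV input/output for all stages, and a
    command-line pipeline (simulate / allocate / validate / report).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
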