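Package: promscan
Title: Detecting Patient-Reported Outcome and Experience Measures in
    Clinical-Trial Registry Outcome Descriptions
Version: 0.1.0
Authors@R:
    person("promscan", "maintainers", email = "promscan@example.org",
           role = c("aut", "cre"))
Description: Tools for mining clinical-trial registry records for
    patient-reported outcome measures (PROMs) and patient-reported
    experience measures (PREMs). Implements an expert-style lexicon and
    generic-term matcher, a trainable bag-of-words outcome classifier with
    balanced classes and a train/validation/test split, a gold-standard
    annotation workflow with Cohen's kappa and adjudication, a
    confusion-matrix evaluation harness with confidence intervals and an
    algorithm-comparison chi-square test, rule-assisted instrument mention
    extraction with trigram-cosine normalization to a canonical lexicon,
    free-text cancer-site recoding via k-means clustering and prototype
    classification, study-level uptake analytics (yearly trends, bivariate
    tests, stratified multivariate logistic regression, missingness
    checks), and a seeded synthetic registry corpus generator with planted
    ground truth for end-to-end testing without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
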