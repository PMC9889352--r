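Package: mlnqa
Title: Practice Variation Analysis for Mediastinal Lymph Node FNA Cytology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality-assurance analytics for endobronchial/endoscopic
    ultrasound guided mediastinal lymph node fine needle aspiration (EBUS/EUS
    MLN-FNA) cytology. Classifies free-text cytopathology reports into
    diagnostic categories and IASLC/AJCC nodal stations with a hierarchical
    dictionary string matcher, groups categories into mutually exclusive
    severity tiers (malignant, suspicious, insufficient, benign), tabulates
    per-provider diagnostic rates, draws funnel plots and control charts
    centred on the group median rate with exact binomial control limits, fits
    multivariable categorical logistic regressions of submitting physician,
    pathologist and station effects, and generates ground-truth synthetic
    report corpora for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
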