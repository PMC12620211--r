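Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for pharmacovigilance signal detection on
    FDA Adverse Event Reporting System (FAERS) style quarterly extracts:
    ingestion and validation of the "$"-delimited ASCII tables, report
    deduplication by CASEID/FDA_DT/PRIMARYID, cohort selection by suspect
    drug, indication and MedDRA System Organ Class, four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio,
    Bayesian confidence propagation neural network information component,
    and empirical Bayes geometric mean) with combined screening criteria,
    descriptive and comparative reporting, concomitant-medication
    sensitivity re-analysis, and a synthetic FAERS generator with planted
    drug-event reporting-rate ratios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
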