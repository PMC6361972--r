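Package: emtscreen
Title: Co-Culture High-Content Screen Analysis for EMT-Selective Cytotoxic Compounds
Version: 0.1.0
Authors@R:
    person("Screen", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis chain for a two-colour co-culture
    high-content cytotoxicity screen that searches for compounds
    selectively killing cells in an epithelial-to-mesenchymal-transition
    (EMT) like state. Provides per-plate normalization to untreated
    controls, assay quality statistics (Z'-factor, S/N, S/B),
    three-criterion selectivity hit classification, four-parameter
    logistic dose-response fitting with absolute IC50 and
    growth-rate-corrected GR50, fold-selectivity, population doubling
    level computation, sensitive/resistant panel classification, and a
    from-scratch permutation-based gene set enrichment analysis.
    Seeded synthetic-data generators emulate plate counts, dose-response
    tables, growth curves and expression matrices so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
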