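Package: ntscreen
Title: Non-Target LC-HRMS Screening, Annotation Confidence and Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline workflow for studying disease metabolomes and exposomes from
    aligned LC-HRMS feature tables. Provides molecular formula arithmetic and adduct
    m/z computation, theoretical isotope patterns, NIST-dialect MSP spectral library
    input/output, pooled-QC relative standard deviation filtering, MS/MS library search
    with cosine dot-product and fragment-presence scores, GenForm-style molecular
    formula enumeration with isotope and MS/MS consistency scoring, suspect-list
    screening by exact mass and adduct, a rule engine for identification confidence
    levels (2a-5) under three screening schemes, MetaboAnalyst-style statistics
    (IQR filtering, sum normalization, Pareto scaling, Welch t-tests, fold changes,
    NIPALS PLS-DA/O-PLS-DA with VIP scores), InChIKey set-overlap reports,
    hypergeometric pathway over-representation, and a ground-truth synthetic cohort
    generator that exercises every confidence level end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
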