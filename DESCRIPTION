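Package: papmeth
Title: DNA Methylation Marker Discovery and Ovarian Cancer Risk Scoring
    from Cervical Scrapings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discovering ovarian-cancer-specific DNA
    hypermethylation markers across heterogeneous methylome platforms and
    translating quantitative methylation-specific PCR (qMSP) measurements
    from cervical scrapings into a logistic risk score. Quantifies
    MBD-seq read density in windows centered on transcription start
    sites, calls highly differentially methylated genes on 450K-style
    beta-value matrices with promoter-level aggregation, intersects
    marker sets across datasets, clusters candidate profiles, applies
    pooled-DNA qMSP verification rules, and fits cross-validated
    logistic risk models with ROC-based cutoff selection and bootstrap
    confidence intervals. Includes a synthetic-cohort generator with
    known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
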