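Package: cohortMet
Title: Trans-Cohort Plasma Metabolomics Biomarker Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential abundance analysis, consensus feature selection and
    network-based community analysis for case-control plasma metabolomics
    studies replicated across independent cohorts. Provides a
    SummarizedExperiment-based container for metabolite abundance matrices
    with Metabolon-style pathway annotations, per-cohort Mann-Whitney/FDR
    statistics with Glass-delta effect sizes, three complementary feature
    selection engines (rank tests, PLS-DA variable importance, Boruta-style
    random-forest selection), cross-cohort consensus biomarker nomination
    with drug exclusion and direction-concordance checks, Spearman
    co-abundance networks with Leiden community detection, Monti-style
    resampled consensus clustering, hypergeometric pathway-term
    over-representation, and a synthetic paired-cohort generator with full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ranger,
    pROC,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
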