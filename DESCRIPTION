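Package: methylaber
Title: Methylation Subtyping and Per-Gene Aberration Calling Against a
    Normal Reference Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Illumina 450K-style DNA methylation
    beta-value matrices from tumour cohorts: M-value conversion, low-rank
    imputation of incomplete data, sex-chromosome probe removal,
    top-variance probe selection and unsupervised hierarchical subtyping;
    Wilcoxon rank-sum differential methylation between subtype groups; a
    per-gene rank-one multiplicative decomposition of promoter methylation
    changes relative to a normal skeletal-muscle reference panel, with
    z-scores against the panel and plug-in FDR-controlled aberration
    calls; and cohort statistics linking methylation clusters to mutation
    and survival data (Fisher exact enrichment, t-tests, Kaplan-Meier and
    log-rank comparisons). Includes a synthetic-cohort generator with
    planted cluster structure, methylation aberrations and
    cluster-correlated mutation and survival tables so every stage has a
    recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
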