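Package: methylAH
Title: Aqueous Humor cfDNA Methylation Analysis for Retinoblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing DNA methylation array beta values from
    retinoblastoma tumors and aqueous-humor cell-free DNA liquid biopsies.
    Covers beta-value computation from methylated/unmethylated intensities,
    detection-p masking, probe filtering and cross-platform intersection,
    LUMP-based tumor purity gating, probe-level differential methylation
    (two-sided Welch's t-test with delta-beta effect filters), genic-region
    classification and enrichment, integration of promoter/gene-body
    methylation with differential expression to call methylation-regulated
    genes, variance-ranked probe selection, hierarchical clustering and
    classical MDS, prognostic signature-panel derivation with Cluster A/B
    assignment and exact outcome tests, paired-sample concordance (squared
    Pearson correlation) and input-mass titration curves. Includes a
    synthetic-cohort generator with planted effects and ground-truth records
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
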