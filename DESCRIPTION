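Package: methcap
Title: CpG-Island-Centered Analysis of Enrichment-Captured cfDNA Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing methylation-enrichment (MBD/MeDIP capture)
    sequencing of plasma cell-free DNA around CpG islands: spike-in capture
    quality control, CpG feature annotation (islands, shores, shelves,
    inter-CpG), fragment-to-feature counting with TPM normalization,
    negative-binomial Wald differential methylation with
    Benjamini-Hochberg FDR and fold-change gating, array-style beta-value
    harmonization and island aggregation, set intersection to derive
    tumor-derived and cancer-type-specific hypermethylated islands, and a
    repeated class-balanced consensus-LASSO classifier with ROC evaluation.
    Includes a synthetic-data generator emulating the statistical structure
    of capture-sequencing count data, array beta values, and spike-in qPCR
    controls, so the full pipeline can be exercised and calibrated without
    restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    pROC
Config/testthat/edition: 3
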