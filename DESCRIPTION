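Package: scgpcr
Title: Single-Cell GPCR Expression Profiling from Microfluidic qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell G-protein-coupled receptor (GPCR)
    expression profiling of vascular cells by microfluidic quantitative RT-PCR.
    Provides marker-panel cell-identity gating with contamination reporting,
    limit-of-detection anchored transformation of cycle-threshold (Ct) values to
    an expression scale, expression-frequency and receptors-per-cell
    heterogeneity statistics, k-means clustering on correlation-matrix features
    with binomial cluster-marker testing and t-SNE embedding, Spearman
    co-expression network construction, promoter position-weight-matrix scanning
    with gene-set enrichment z-tests, NanoString-style bulk count normalization
    including geNorm reference-gene stability, and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rtsne,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    Biostrings
Config/testthat/edition: 3
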