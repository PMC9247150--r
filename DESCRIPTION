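Package: vagex
Title: Quality Control, Hurdle-Model Differential Expression and
    Detection-Rate Statistics for Single-Nucleus RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of multi-sample single-nucleus RNA-seq
    UMI count matrices: per-sample quality-control filtering (gene
    detection, per-nucleus gene counts, mitochondrial fraction and
    transcript-count outlier rules), log normalization, covariate-adjusted
    two-part (hurdle) differential-expression testing within annotated
    cell clusters, cell-detection-rate (CDR) statistics computed from the
    binarized count matrix with cell-level Wilcoxon rank-sum and
    sample-level t tests, and extraction of vastly altered genes (VAGs)
    as the intersection of differentially expressed genes and genes with
    significant detection-rate changes. Includes a seeded synthetic-data
    generator with planted expression and detection effects so the whole
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
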