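Package: clonofate
Title: Clonotype Fate Bias and Reference-Map Projection for Paired
    scRNA-seq/scTCR-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of paired single-cell transcriptome and T cell
    receptor (TCR) repertoire data from virus-specific CD4+ T cells.
    Provides quality control with fixed thresholds and per-sample
    percentile trimming, construction of a simplified reference map
    (variable-gene selection with exclusion lists, per-batch
    standardization, PCA embedding, graph clustering and
    signature-guided subtype annotation), projection of query cells into
    the reference with k-nearest-neighbour label transfer and
    novel-state diagnostics, binomial downsampling for sequencing-depth
    robustness, clonotype assembly from paired alpha/beta CDR3
    sequences, repertoire expansion and overlap summaries, and a
    clonotype fate-bias statistic with a permutation-calibrated null and
    Z-scores. Includes a synthetic-cohort generator emulating the
    clonal and transcriptional structure of such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    BiocNeighbors,
    scran,
    Seurat,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
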