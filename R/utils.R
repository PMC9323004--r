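## Internal numerical helpers shared across modules.

#' Log-normalize a UMI count matrix
#'
#' Counts are scaled per cell to `scaleFactor` total counts and
#' log-transformed with `log1p` (counts-per-10k convention). Cells with
#' zero total counts are left as all-zero.
#'
#' @param counts sparse or dense gene x cell matrix of nonnegative counts.
#' @param scaleFactor library-size scaling constant (default 1e4).
#' @return matrix of the same shape, log-normalized; sparse in, sparse out.
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  if (methods::is(counts, "sparseMatrix")) {
    x <- methods::as(counts, "CsparseMatrix")
    ncol_entries <- diff(x@p)
    x@x <- log1p(x@x / rep.int(cs, ncol_entries) * scaleFactor)
    x
  } else {
    log1p(sweep(as.matrix(counts), 2L, cs, "/") * scaleFactor)
  }
}

## counts accessor tolerant to plain matrices and SCE
.getCounts <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    x
  }
}

.getSamples <- function(x) {
  if (methods::is(x, "SummarizedExperiment") &&
      "sample" %in% colnames(SummarizedExperiment::colData(x))) {
    as.character(SummarizedExperiment::colData(x)$sample)
  } else {
    rep("sample1", ncol(x))
  }
}

## row-wise max of a numeric matrix (ties resolved to first column)
.rowMax <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
}

## squared Euclidean cross-distances between rows of a and rows of b
.crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

.checkSeed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  as.integer(seed)
}
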