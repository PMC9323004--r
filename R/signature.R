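## Rank-based gene-signature scoring (Mann-Whitney-U-derived, UCell-style).

#' Score a gene signature per cell
#'
#' For each cell, genes are ranked by decreasing raw expression (average
#' ranks on ties); ranks beyond `maxRank` are truncated. The score is a
#' min-max normalized Mann-Whitney U statistic of the signature's ranks:
#' 1 when the signature occupies the top ranks of the cell, 0 when every
#' signature gene lies beyond `maxRank`, and approximately 0.5 for a
#' random gene set.
#'
#' @param counts SingleCellExperiment or gene x cell count matrix.
#' @param genes character vector of signature genes.
#' @param maxRank rank truncation (default 1500).
#' @return numeric vector, one score in \[0, 1\] per cell.
#' @export
scoreSignature <- function(counts, genes, maxRank = 1500) {
  m <- .getCounts(counts)
  sig <- intersect(genes, rownames(m))
  if (length(sig) == 0L) {
    warning("signature has no genes in common with the matrix; scores are 0")
    return(setNames(rep(0, ncol(m)), colnames(m)))
  }
  dense <- as.matrix(m)
  n <- length(sig)
  sig_idx <- match(sig, rownames(m))
  r_min <- n * (n + 1) / 2
  r_max <- n * (maxRank + 1)
  scores <- vapply(seq_len(ncol(dense)), function(j) {
    r <- rank(-dense[, j], ties.method = "average")
    r[r > maxRank] <- maxRank + 1
    R <- sum(r[sig_idx])
    1 - (R - r_min) / (r_max - r_min)
  }, 0)
  scores[scores < 0] <- 0
  scores[scores > 1] <- 1
  setNames(scores, colnames(m))
}
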