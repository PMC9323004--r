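## Cell-level quality control: fixed thresholds followed by a per-sample
## percentile trim of extreme outliers.

#' Per-cell QC statistics
#'
#' Computes detected genes, total UMIs, and the percentage of counts from
#' mitochondrial and ribosomal genes (on the total-count denominator).
#' Cells with zero total counts get all-zero statistics and are flagged.
#'
#' @param counts gene x cell count matrix or SingleCellExperiment (the
#'   `sample` colData column, if present, is carried along).
#' @param mitoPrefix gene-symbol prefix for mitochondrial genes
#'   (default `"mt-"`).
#' @param riboPrefixes prefixes for ribosomal genes (default
#'   `c("Rps", "Rpl")`).
#' @return data.frame with one row per cell: `cell`, `sample`, `n_genes`,
#'   `n_umi`, `pct_mito`, `pct_ribo`, `zero_total`.
#' @export
computeCellQC <- function(counts, mitoPrefix = "mt-",
                          riboPrefixes = c("Rps", "Rpl")) {
  m <- .getCounts(counts)
  samples <- .getSamples(counts)
  genes <- rownames(m)
  if (is.null(genes)) stop("count matrix must carry gene names")
  mito <- .matchPrefixes(genes, mitoPrefix)
  ribo <- .matchPrefixes(genes, riboPrefixes)
  n_umi <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito_counts <- if (length(mito)) {
    Matrix::colSums(m[mito, , drop = FALSE])
  } else {
    rep(0, ncol(m))
  }
  ribo_counts <- if (length(ribo)) {
    Matrix::colSums(m[ribo, , drop = FALSE])
  } else {
    rep(0, ncol(m))
  }
  zero_total <- n_umi == 0
  denom <- ifelse(zero_total, 1, n_umi)
  data.frame(
    cell = if (is.null(colnames(m))) as.character(seq_len(ncol(m))) else colnames(m),
    sample = samples,
    n_genes = as.integer(n_genes),
    n_umi = as.integer(n_umi),
    pct_mito = 100 * mito_counts / denom,
    pct_ribo = 100 * ribo_counts / denom,
    zero_total = zero_total,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Apply the two-step QC filter
#'
#' Step 1 applies fixed thresholds: detected genes > `minGenes`, UMIs
#' strictly between `minUMI` and `maxUMI`, ribosomal percentage <
#' `maxRibo`, mitochondrial percentage < `maxMito`. Each rejected cell is
#' attributed to the first rule it violates, in that order. Step 2,
#' applied once to the survivors of step 1, removes per sample every cell
#' strictly outside the `[pctLow, pctHigh]` percentile interval
#' (linear-interpolation quantiles, bounds inclusive) of any of the four
#' statistics. The percentile step is not idempotent and is applied
#' exactly once.
#'
#' @param stats data.frame from [computeCellQC()].
#' @param minGenes,minUMI,maxUMI,maxRibo,maxMito fixed thresholds
#'   (defaults 700, 1500, 15000, 50, 10).
#' @param pctLow,pctHigh trimming percentiles (defaults 1 and 99); set
#'   `percentile = FALSE` to skip step 2.
#' @param percentile logical; apply step 2 (default TRUE).
#' @return list with `kept` (cell ids), `rejections` (named counts per
#'   rule: `genes`, `umi`, `ribo`, `mito`, `percentile`), and `details`
#'   (per-cell data.frame with `status` and attributed `rule`).
#' @export
applyQCFilters <- function(stats, minGenes = 700, minUMI = 1500,
                           maxUMI = 15000, maxRibo = 50, maxMito = 10,
                           pctLow = 1, pctHigh = 99, percentile = TRUE) {
  req <- c("cell", "sample", "n_genes", "n_umi", "pct_mito", "pct_ribo")
  if (!all(req %in% colnames(stats))) {
    stop("stats must contain columns: ", paste(req, collapse = ", "))
  }
  rule <- rep(NA_character_, nrow(stats))
  viol_genes <- !(stats$n_genes > minGenes)
  viol_umi <- !(stats$n_umi > minUMI & stats$n_umi < maxUMI)
  viol_ribo <- !(stats$pct_ribo < maxRibo)
  viol_mito <- !(stats$pct_mito < maxMito)
  rule[viol_mito] <- "mito"
  rule[viol_ribo] <- "ribo"
  rule[viol_umi] <- "umi"
  rule[viol_genes] <- "genes"   # first-violated wins: assigned last
  pass1 <- is.na(rule)

  if (percentile) {
    params <- c("n_genes", "n_umi", "pct_mito", "pct_ribo")
    for (s in unique(stats$sample)) {
      in_sample <- pass1 & stats$sample == s
      if (!any(in_sample)) {
        warning("sample '", s, "' empty after fixed thresholds; ",
                "percentile trim skipped")
        next
      }
      out <- rep(FALSE, nrow(stats))
      for (p in params) {
        v <- stats[[p]][in_sample]
        qs <- stats::quantile(v, probs = c(pctLow, pctHigh) / 100,
                              type = 7, names = FALSE)
        out[in_sample] <- out[in_sample] | v < qs[1] | v > qs[2]
      }
      rule[out] <- "percentile"
    }
  }

  kept <- stats$cell[is.na(rule)]
  rejections <- vapply(c("genes", "umi", "ribo", "mito", "percentile"),
                       function(r) sum(rule == r, na.rm = TRUE), 0L)
  details <- data.frame(cell = stats$cell, sample = stats$sample,
                        status = ifelse(is.na(rule), "kept", "rejected"),
                        rule = rule, stringsAsFactors = FALSE)
  list(kept = kept, rejections = rejections, details = details)
}
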