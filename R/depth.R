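## Binomial thinning of count matrices and the sequencing-depth
## robustness curve for projection-based classification.

#' Downsample a count matrix by binomial thinning
#'
#' Each UMI is retained independently with probability `p` (binomial
#' thinning per matrix entry), emulating a shallower sequencing run.
#'
#' @param counts SingleCellExperiment or sparse count matrix.
#' @param p retention probability in (0, 1]; `p = 1` returns the input
#'   unchanged.
#' @param seed RNG seed.
#' @return object of the same class with thinned integer counts.
#' @export
downsampleCounts <- function(counts, p, seed = 42) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("'p' must be a single number in (0, 1]")
  }
  if (p == 1) return(counts)
  m <- .getCounts(counts)
  set.seed(.checkSeed(seed))
  x <- methods::as(m, "CsparseMatrix")
  x@x <- as.numeric(stats::rbinom(length(x@x), size = as.integer(x@x),
                                  prob = p))
  x <- Matrix::drop0(x)
  if (methods::is(counts, "SummarizedExperiment")) {
    out <- counts
    SummarizedExperiment::assay(out, "counts") <- x
    out
  } else {
    x
  }
}

#' Classification agreement as a function of sequencing depth
#'
#' For each retained-depth fraction `p`, thins the query counts, re-runs
#' projection and kNN classification, and reports the fraction of cells
#' whose subtype call is unchanged relative to the full-depth labels,
#' together with the median detected genes and UMIs per cell at that
#' depth. When `related` groups subtypes (e.g. effector and memory
#' states of the same lineage), a lenient agreement counting
#' within-group swaps as agreement is reported as well.
#'
#' @param query SingleCellExperiment or count matrix.
#' @param ref a [ReferenceMap-class].
#' @param fractions depth fractions in (0, 1].
#' @param k classification neighbours (default 20).
#' @param seed RNG seed (one thinning stream per fraction).
#' @param related optional named character mapping subtype -> lineage
#'   group for the lenient metric.
#' @return data.frame (`AgreementCurve`): `depth_fraction`, `agreement`,
#'   `lenient_agreement`, `median_genes`, `median_umis`.
#' @export
depthRobustness <- function(query, ref, fractions, k = 20, seed = 42,
                            related = NULL) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  seed <- .checkSeed(seed)
  full <- classifySubtypes(projectCells(query, ref), ref, k = k)
  full_lab <- as.character(full@predicted)
  lenient_of <- function(lab) {
    if (is.null(related)) lab else ifelse(lab %in% names(related),
                                          related[lab], lab)
  }
  rows <- lapply(seq_along(fractions), function(i) {
    p <- fractions[i]
    thinned <- downsampleCounts(query, p, seed = seed + i)
    m <- .getCounts(thinned)
    res <- classifySubtypes(projectCells(thinned, ref), ref, k = k)
    lab <- as.character(res@predicted)
    data.frame(
      depth_fraction = p,
      agreement = mean(lab == full_lab),
      lenient_agreement = mean(lenient_of(lab) == lenient_of(full_lab)),
      median_genes = stats::median(Matrix::colSums(m > 0)),
      median_umis = stats::median(Matrix::colSums(m))
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("AgreementCurve", class(out))
  out
}
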