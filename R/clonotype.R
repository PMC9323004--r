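## Clonotype assembly from paired chains, expansion profiles and
## repertoire overlap across samples.

#' Assemble clonotypes from per-cell TCR chains
#'
#' Cells with a productive alpha and a productive beta chain are assigned
#' a clonotype keyed by the concatenated CDR3 pair (amino-acid and
#' nucleotide keys). Cells with more than one productive chain at a
#' locus are resolved by the chain-selection policy (default: the chain
#' with most UMIs; ties by CDR3 string order for determinism). Cells
#' lacking a productive chain at either locus are left unassigned with a
#' reason code. Clonotypes are formed within samples.
#'
#' @param chains data.frame in the [readTCRContigs()] layout (columns
#'   `barcode`, `locus`, `cdr3_aa`, `cdr3_nt`, `productive`, `umis`,
#'   `sample`).
#' @param policy chain-selection policy; only `"umis"` is implemented.
#' @return list with `clonotypes` (data.frame: `sample`, `key_aa`,
#'   `key_nt`, `size`) and `assignment` (per-cell data.frame: `cell`,
#'   `sample`, `barcode`, `key_aa`, `key_nt`, `assigned`, `reason`).
#' @export
assembleClonotypes <- function(chains, policy = "umis") {
  if (!identical(policy, "umis")) stop("unknown chain-selection policy")
  req <- c("barcode", "locus", "cdr3_aa", "cdr3_nt", "productive", "umis")
  if (!all(req %in% colnames(chains))) {
    stop("chains must contain columns: ", paste(req, collapse = ", "))
  }
  if (!"sample" %in% colnames(chains) || all(is.na(chains$sample))) {
    chains$sample <- "sample1"
  }
  prod <- chains[chains$productive, , drop = FALSE]
  ## deterministic chain selection: highest UMIs, then CDR3 nt order
  prod <- prod[order(prod$sample, prod$barcode, prod$locus,
                     -prod$umis, prod$cdr3_nt), , drop = FALSE]
  first <- !duplicated(prod[, c("sample", "barcode", "locus")])
  best <- prod[first, , drop = FALSE]

  cell_key <- unique(chains[, c("sample", "barcode")])
  cell_key$cell <- paste(cell_key$sample, cell_key$barcode, sep = ":")
  idx <- paste(best$sample, best$barcode, best$locus, sep = ":")
  a_row <- match(paste(cell_key$sample, cell_key$barcode, "alpha", sep = ":"), idx)
  b_row <- match(paste(cell_key$sample, cell_key$barcode, "beta", sep = ":"), idx)

  has_a <- !is.na(a_row)
  has_b <- !is.na(b_row)
  reason <- rep(NA_character_, nrow(cell_key))
  reason[!has_a & has_b] <- "missing alpha"
  reason[has_a & !has_b] <- "missing beta"
  reason[!has_a & !has_b] <- "no productive chains"
  assigned <- has_a & has_b

  key_aa <- rep(NA_character_, nrow(cell_key))
  key_nt <- rep(NA_character_, nrow(cell_key))
  key_aa[assigned] <- paste(best$cdr3_aa[a_row[assigned]],
                            best$cdr3_aa[b_row[assigned]], sep = "_")
  key_nt[assigned] <- paste(best$cdr3_nt[a_row[assigned]],
                            best$cdr3_nt[b_row[assigned]], sep = "_")

  assignment <- data.frame(
    cell = cell_key$cell, sample = cell_key$sample,
    barcode = cell_key$barcode, key_aa = key_aa, key_nt = key_nt,
    assigned = assigned, reason = reason, stringsAsFactors = FALSE,
    row.names = NULL)

  asg <- assignment[assignment$assigned, , drop = FALSE]
  clonotypes <- if (nrow(asg)) {
    agg <- stats::aggregate(list(size = asg$cell),
                            by = list(sample = asg$sample,
                                      key_aa = asg$key_aa,
                                      key_nt = asg$key_nt),
                            FUN = length)
    agg[order(agg$sample, -agg$size, agg$key_nt), , drop = FALSE]
  } else {
    data.frame(sample = character(0), key_aa = character(0),
               key_nt = character(0), size = integer(0))
  }
  rownames(clonotypes) <- NULL
  list(clonotypes = clonotypes, assignment = assignment)
}

.default_bins <- data.frame(
  label = c("1", "2-5", "6-20", "21-100", ">100"),
  lo = c(1, 2, 6, 21, 101),
  hi = c(1, 5, 20, 100, Inf)
)

#' Clonal-space occupancy by expansion class
#'
#' Per sample, the number and fraction of cells belonging to clonotypes
#' in each size class. Default classes: 1, 2-5, 6-20, 21-100, >100.
#'
#' @param clonotypes data.frame from [assembleClonotypes()] (`sample`,
#'   `size` columns required).
#' @param bins data.frame with `label`, `lo`, `hi` defining disjoint,
#'   gap-free size classes covering all of `>= 1`.
#' @return data.frame: `sample`, `class`, `n_clones`, `n_cells`,
#'   `fraction` (of the sample's cells).
#' @export
expansionProfile <- function(clonotypes, bins = .default_bins) {
  bins <- bins[order(bins$lo), , drop = FALSE]
  if (any(bins$lo[-1] != bins$hi[-nrow(bins)] + 1) || bins$lo[1] != 1) {
    stop("bins must partition the clone sizes >= 1 without gaps or overlap")
  }
  out <- list()
  for (s in unique(clonotypes$sample)) {
    cl <- clonotypes[clonotypes$sample == s, ]
    total <- sum(cl$size)
    for (b in seq_len(nrow(bins))) {
      in_bin <- cl$size >= bins$lo[b] & cl$size <= bins$hi[b]
      out[[length(out) + 1L]] <- data.frame(
        sample = s, class = bins$label[b],
        n_clones = sum(in_bin), n_cells = sum(cl$size[in_bin]),
        fraction = sum(cl$size[in_bin]) / total,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Repertoire overlap and privacy across samples
#'
#' Among clonotypes with at least `minCells` cells, counts exact key
#' matches across samples. Clonotypes seen in one sample are private,
#' in two or more shared, and in at least three public.
#'
#' @param clonotypes data.frame from [assembleClonotypes()] covering
#'   >= 2 samples.
#' @param key `"nt"` (default) or `"aa"`: which CDR3 pair key to match.
#' @param minCells minimum clone size considered (default 3).
#' @return list with `clones` (key, `n_samples`, `samples`, `label`),
#'   `summary` (counts of private/shared/public and total), and
#'   `pairwise` (sample x sample shared-clone counts).
#' @export
repertoireOverlap <- function(clonotypes, key = c("nt", "aa"), minCells = 3) {
  key <- match.arg(key)
  kcol <- paste0("key_", key)
  samples <- unique(clonotypes$sample)
  if (length(samples) < 2L) stop("overlap requires at least 2 samples")
  cl <- clonotypes[clonotypes$size >= minCells, , drop = FALSE]
  sample_sets <- lapply(split(cl$sample, cl[[kcol]]), unique)
  n_samples <- lengths(sample_sets)
  label <- ifelse(n_samples >= 3, "public",
                  ifelse(n_samples >= 2, "shared", "private"))
  clones <- data.frame(
    key = names(sample_sets),
    n_samples = as.integer(n_samples),
    samples = vapply(sample_sets, function(x) paste(sort(x), collapse = ","), ""),
    label = label, stringsAsFactors = FALSE, row.names = NULL)
  pairwise <- matrix(0L, length(samples), length(samples),
                     dimnames = list(samples, samples))
  for (ss in sample_sets) {
    for (i in ss) for (j in ss) {
      if (i != j) pairwise[i, j] <- pairwise[i, j] + 1L
    }
  }
  list(
    clones = clones,
    summary = c(n_clonotypes = nrow(clones),
                private = sum(label == "private"),
                shared = sum(n_samples >= 2),
                public = sum(n_samples >= 3)),
    pairwise = pairwise
  )
}
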