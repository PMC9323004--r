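## The clonotype fate-bias statistic, its permutation-calibrated null and
## per-clonotype Z-scores.

#' Subtype frequency distribution
#'
#' Frequencies of subtype labels over a set of cells, optionally on a
#' fixed label universe (absent labels get frequency 0).
#'
#' @param labels character or factor of subtype labels.
#' @param levels optional label universe.
#' @return named numeric summing to 1.
#' @export
subtypeDistribution <- function(labels, levels = NULL) {
  labels <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(labels))
  tab <- table(factor(labels, levels = levels))
  out <- as.numeric(tab) / length(labels)
  setNames(out, levels)
}

#' Clonotype bias statistic
#'
#' `c = max_i (f_i - q_i) / (1 - q_i)`, clamped below at 0, where `f` is
#' the clonotype's subtype composition and `q` the background subtype
#' distribution of the whole sample. A bias of 1 means the clonotype is
#' composed uniquely of cells of one subtype; 0 means its composition
#' matches the background exactly. The predominant subtype is the argmax
#' (ties resolved toward the larger `f_i`, then label order).
#'
#' @param f named numeric clonotype composition (sums to 1).
#' @param q named numeric background distribution over the same labels,
#'   all entries < 1.
#' @return list with `c` and `predominant`.
#' @export
clonotypeBias <- function(f, q) {
  if (is.null(names(f)) || is.null(names(q))) {
    if (length(f) != length(q)) stop("f and q must share a label set")
    names(f) <- names(q) <- paste0("subtype", seq_along(f))
  }
  if (!setequal(names(f), names(q))) stop("f and q must share a label set")
  f <- f[names(q)]
  if (any(q >= 1)) stop("degenerate background: some q_i = 1")
  ci <- (f - q) / (1 - q)
  cand <- which(ci == max(ci))
  if (length(cand) > 1L) cand <- cand[f[cand] == max(f[cand])]
  list(c = max(0, max(ci)), predominant = names(q)[cand[1L]])
}

#' Normal tail probability of a bias Z-score
#'
#' @param z Z-score(s).
#' @param sides 1 (upper tail) or 2 (two-sided).
#' @return tail probability; at `z = 5` the two-sided value is ~6e-7.
#' @export
biasTailProbability <- function(z, sides = 2) {
  if (sides == 1) {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(-abs(z))
  }
}

## geometric bin edges used when a clone size has too few null draws
.geom_bins <- data.frame(
  lo = c(1, 2, 6, 10, 15, 22, 47, 101),
  hi = c(1, 5, 9, 14, 21, 46, 100, Inf)
)

#' Permutation null of the clonotype bias, binned by clone size
#'
#' Shuffles cell-subtype labels across cells `nPerm` times, reassembles
#' clones at their observed sizes, computes the bias statistic per clone
#' and permutation, and summarizes mean and standard deviation per clone
#' size bin. Sizes represented by at least 30 distinct clones form their
#' own exact-size bin; rarer sizes fall into geometric bins (1, 2-5,
#' 6-9, 10-14, 15-21, 22-46, 47-100, >100), and bins still holding fewer
#' than 30 null draws are merged with a neighbour (with a warning).
#'
#' @param cloneSizes integer clone sizes; must sum to the number of
#'   cells.
#' @param cellSubtypes subtype label per cell, grouped by clone in the
#'   order of `cloneSizes` (the grouping only fixes which label multiset
#'   is permuted, so any grouping consistent with the sizes is
#'   equivalent).
#' @param nPerm number of permutations (>= 100, default 1000).
#' @param seed RNG seed.
#' @param minSize smallest clone size for which null values are computed
#'   (default 1).
#' @return data.frame with `label`, `lo`, `hi`, `n_clones`, `n_obs`,
#'   `mean`, `sd` per bin; background frequencies and parameters as
#'   attributes.
#' @export
permutationNull <- function(cloneSizes, cellSubtypes, nPerm = 1000,
                            seed = 42, minSize = 1) {
  cloneSizes <- as.integer(cloneSizes)
  n <- length(cellSubtypes)
  if (sum(cloneSizes) != n) {
    stop("clone sizes must sum to the number of cell labels")
  }
  if (nPerm < 100) stop("nPerm must be at least 100")
  set.seed(.checkSeed(seed))
  lab <- factor(as.character(cellSubtypes))
  lev <- levels(lab)
  lab_int <- as.integer(lab)
  q <- as.numeric(table(lab)) / n
  names(q) <- lev

  big <- which(cloneSizes >= minSize)
  if (length(big) == 0L) stop("no clones at or above minSize")
  sizes_big <- cloneSizes[big]
  clone_of_cell <- rep(seq_along(cloneSizes), cloneSizes)
  cell_pos <- which(clone_of_cell %in% big)
  big_idx <- match(clone_of_cell[cell_pos], big)
  nbig <- length(big)
  nlev <- length(lev)

  cmat <- matrix(0, nrow = nbig, ncol = nPerm)
  one_minus_q <- 1 - q
  if (any(one_minus_q == 0)) stop("degenerate background: some q_i = 1")
  for (p in seq_len(nPerm)) {
    labs <- lab_int[sample.int(n)][cell_pos]
    tab <- tabulate(big_idx + nbig * (labs - 1L), nbins = nbig * nlev)
    fm <- matrix(tab, nrow = nbig, ncol = nlev) / sizes_big
    bm <- sweep(sweep(fm, 2L, q, "-"), 2L, one_minus_q, "/")
    cv <- .rowMax(bm)
    cmat[, p] <- pmax(cv, 0)
  }

  ## bin assignment per clone size: a size gets its own bin only when
  ## enough distinct clones share it; rarer sizes pool into geometric bins
  usz <- sort(unique(sizes_big))
  nclones_of_size <- vapply(usz, function(s) sum(sizes_big == s), 0)
  own <- usz[nclones_of_size >= 30]
  bins <- list()
  for (s in own) {
    bins[[length(bins) + 1L]] <- list(lo = s, hi = s)
  }
  rare <- setdiff(usz, own)
  if (length(rare)) {
    for (b in seq_len(nrow(.geom_bins))) {
      in_b <- rare[rare >= .geom_bins$lo[b] & rare <= .geom_bins$hi[b]]
      if (length(in_b)) {
        bins[[length(bins) + 1L]] <- list(lo = .geom_bins$lo[b],
                                          hi = .geom_bins$hi[b])
      }
    }
  }
  ord <- order(vapply(bins, `[[`, 0, "lo"))
  bins <- bins[ord]

  stat_of <- function(b) {
    rows <- which(sizes_big >= b$lo & sizes_big <= b$hi)
    v <- cmat[rows, , drop = FALSE]
    list(n_clones = length(rows), n_obs = length(v),
         mean = mean(v), sd = stats::sd(as.numeric(v)))
  }
  stats_list <- lapply(bins, stat_of)
  ## merge under-populated bins with a neighbour
  repeat {
    small <- which(vapply(stats_list, `[[`, 0, "n_obs") < 30)
    if (length(small) == 0L || length(bins) == 1L) break
    i <- small[1L]
    j <- if (i == length(bins)) i - 1L else i + 1L
    warning("clone-size bin with <30 null draws merged with neighbour")
    merged <- list(lo = min(bins[[i]]$lo, bins[[j]]$lo),
                   hi = max(bins[[i]]$hi, bins[[j]]$hi))
    bins <- c(bins[-c(i, j)], list(merged))
    bins <- bins[order(vapply(bins, `[[`, 0, "lo"))]
    stats_list <- lapply(bins, stat_of)
  }

  out <- data.frame(
    label = vapply(bins, function(b) {
      if (b$lo == b$hi) {
        as.character(b$lo)
      } else if (is.infinite(b$hi)) {
        paste0(">", b$lo - 1)
      } else {
        paste0(b$lo, "-", b$hi)
      }
    }, ""),
    lo = vapply(bins, `[[`, 0, "lo"),
    hi = vapply(bins, `[[`, 0, "hi"),
    n_clones = vapply(stats_list, `[[`, 0, "n_clones"),
    n_obs = vapply(stats_list, `[[`, 0, "n_obs"),
    mean = vapply(stats_list, `[[`, 0, "mean"),
    sd = vapply(stats_list, `[[`, 0, "sd"),
    stringsAsFactors = FALSE)
  attr(out, "background") <- q
  attr(out, "nPerm") <- nPerm
  attr(out, "seed") <- seed
  out
}

#' Clonotype bias Z-scores with permutation-calibrated significance
#'
#' For every clonotype with at least `minSize` cells, computes the bias
#' statistic against the background subtype distribution of its whole
#' sample, compares it with a permutation null of matched clonal
#' structure (mean and standard deviation per clone-size bin), and
#' reports `Z = (c - null_mean) / null_sd`. A clonotype is flagged
#' significant when `Z` strictly exceeds `zThreshold` (so a clone landing
#' exactly at the threshold is not flagged). Bins with zero null
#' standard deviation yield `Z = Inf` when `c` exceeds the null mean and
#' 0 otherwise, flagged in `sd_zero`.
#'
#' @param clone clonotype key per cell.
#' @param subtype subtype label per cell.
#' @param sample optional sample label per cell (analysis and background
#'   are per sample).
#' @param minSize minimum clone size tested (default 10).
#' @param nPerm permutations for the null (default 1000).
#' @param zThreshold significance threshold on Z (default 5; the
#'   two-sided normal tail at 5 is ~6e-7).
#' @param seed RNG seed.
#' @return [S4Vectors::DataFrame] with one row per tested clonotype:
#'   `sample`, `clone`, `size`, `bias`, `predominant`, `null_mean`,
#'   `null_sd`, `z`, `p_one`, `p_two`, `sd_zero`, `significant`.
#'   `metadata()` holds per-sample summaries (expanded and significant
#'   counts, predominant-subtype tallies of the significant clones) and
#'   the null tables.
#' @export
biasZScores <- function(clone, subtype, sample = NULL, minSize = 10,
                        nPerm = 1000, zThreshold = 5, seed = 42) {
  clone <- as.character(clone)
  subtype <- as.character(subtype)
  if (length(clone) != length(subtype)) {
    stop("'clone' and 'subtype' must align per cell")
  }
  if (is.null(sample)) sample <- rep("sample1", length(clone))
  sample <- as.character(sample)
  seed <- .checkSeed(seed)

  rows <- list()
  summaries <- list()
  nulls <- list()
  for (s in unique(sample)) {
    in_s <- sample == s
    cl <- clone[in_s]
    st <- subtype[in_s]
    ord <- order(cl)
    cl <- cl[ord]; st <- st[ord]
    sizes <- as.integer(table(cl))
    keys <- names(table(cl))
    q <- subtypeDistribution(st)

    null <- permutationNull(sizes, st, nPerm = nPerm, seed = seed,
                            minSize = minSize)
    nulls[[s]] <- null

    tested <- which(sizes >= minSize)
    if (length(tested) == 0L) {
      summaries[[s]] <- list(n_expanded = 0L, n_significant = 0L,
                             skew = table(character(0)))
      next
    }
    res_s <- lapply(tested, function(i) {
      members <- st[cl == keys[i]]
      f <- subtypeDistribution(members, levels = names(q))
      cb <- clonotypeBias(f, q)
      bin <- which(null$lo == sizes[i] & null$hi == sizes[i])[1L]
      if (is.na(bin)) bin <- which(null$lo <= sizes[i] & null$hi >= sizes[i])[1L]
      m <- null$mean[bin]; sdv <- null$sd[bin]
      sd_zero <- !is.na(sdv) && sdv == 0
      z <- if (sd_zero) {
        if (cb$c > m) Inf else 0
      } else {
        (cb$c - m) / sdv
      }
      data.frame(sample = s, clone = keys[i], size = sizes[i],
                 bias = cb$c, predominant = cb$predominant,
                 null_mean = m, null_sd = sdv, z = z,
                 p_one = biasTailProbability(z, 1),
                 p_two = biasTailProbability(z, 2),
                 sd_zero = sd_zero,
                 significant = z > zThreshold,
                 stringsAsFactors = FALSE)
    })
    res_s <- do.call(rbind, res_s)
    rows[[s]] <- res_s
    summaries[[s]] <- list(
      n_expanded = nrow(res_s),
      n_significant = sum(res_s$significant),
      skew = table(res_s$predominant[res_s$significant]))
  }
  res <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample = character(0), clone = character(0),
               size = integer(0), bias = numeric(0),
               predominant = character(0), null_mean = numeric(0),
               null_sd = numeric(0), z = numeric(0), p_one = numeric(0),
               p_two = numeric(0), sd_zero = logical(0),
               significant = logical(0))
  }
  out <- S4Vectors::DataFrame(res)
  S4Vectors::metadata(out) <- list(
    summary = summaries, null = nulls,
    params = list(minSize = minSize, nPerm = nPerm,
                  zThreshold = zThreshold, seed = seed))
  out
}
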