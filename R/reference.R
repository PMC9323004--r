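## Reference-map construction: per-condition downsampling, variable-gene
## selection with exclusion lists, per-batch standardization (a simplified
## stand-in for anchor-based integration), PCA embedding, graph clustering
## and signature-guided subtype annotation.

#' Cap the number of cells per condition
#'
#' Randomly retains at most `cap` cells in each condition group (uniform,
#' seeded); groups at or below the cap are kept whole.
#'
#' @param counts SingleCellExperiment or matrix.
#' @param groups condition label per cell, or the name of a colData
#'   column.
#' @param cap maximum cells per group (default 5000).
#' @param seed RNG seed.
#' @return the input subset to the selected cells.
#' @export
capPerCondition <- function(counts, groups, cap = 5000, seed = 42) {
  m <- .getCounts(counts)
  if (length(groups) == 1L && methods::is(counts, "SummarizedExperiment")) {
    groups <- as.character(SummarizedExperiment::colData(counts)[[groups]])
  }
  if (length(groups) != ncol(m)) stop("every cell needs a group label")
  set.seed(.checkSeed(seed))
  keep <- unlist(lapply(split(seq_len(ncol(m)), groups), function(idx) {
    if (length(idx) <= cap) idx else sort(sample(idx, cap))
  }), use.names = FALSE)
  keep <- sort(keep)
  counts[, keep]
}

#' Select variable genes with exclusion lists
#'
#' Ranks genes by the biological component of a fitted mean-variance
#' trend on log-normalized expression (variance-stabilized dispersion)
#' and returns the top `n` after removing the union of the exclusion
#' sets. By default the built-in mitochondrial, ribosomal, heat-shock,
#' interferon-stimulated, cell-cycle and TCR gene lists are excluded.
#'
#' @param counts SingleCellExperiment or count matrix.
#' @param n panel size (default 800).
#' @param exclusionSets list of character vectors to exclude; defaults to
#'   [builtinGeneSets()] minus the `sex` slot.
#' @return character vector of `n` gene symbols.
#' @export
selectVariableGenes <- function(counts, n = 800, exclusionSets = NULL) {
  m <- .getCounts(counts)
  if (is.null(exclusionSets)) {
    bs <- builtinGeneSets(rownames(m))
    exclusionSets <- bs[c("mito", "ribo", "heatshock", "isg", "cycling", "tcr")]
  }
  excluded <- unique(unlist(exclusionSets, use.names = FALSE))
  eligible <- setdiff(rownames(m), excluded)
  if (n > length(eligible)) {
    stop("requested ", n, " variable genes but only ", length(eligible),
         " eligible after exclusions (shortfall ", n - length(eligible), ")")
  }
  logn <- logNormalize(m)
  fit <- scran::modelGeneVar(logn)
  bio <- setNames(fit$bio, rownames(fit))[eligible]
  eligible[order(bio, decreasing = TRUE)][seq_len(n)]
}

## SNN graph + modularity community detection (Seurat convention, on
## which the k/resolution defaults are calibrated); returns 1-based
## integer cluster ids
.snnCluster <- function(scores, k, resolution, seed) {
  rownames(scores) <- paste0("cell", seq_len(nrow(scores)))
  nb <- Seurat::FindNeighbors(scores, k.param = k, verbose = FALSE)
  cl <- Seurat::FindClusters(nb$snn, resolution = resolution,
                             random.seed = seed, verbose = FALSE)[[1L]]
  as.integer(cl)
}

## per-batch standardization of selected rows of a log-normalized matrix
.batchStandardize <- function(logn, batches) {
  x <- as.matrix(logn)
  for (b in unique(batches)) {
    cols <- which(batches == b)
    mu <- rowMeans(x[, cols, drop = FALSE])
    sdv <- apply(x[, cols, drop = FALSE], 1L, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    x[, cols] <- (x[, cols, drop = FALSE] - mu) / sdv
  }
  x
}

#' Build a simplified reference map
#'
#' Log-normalizes counts (per 1e4, `log1p`), standardizes the panel genes
#' within each batch (a simplified stand-in for anchor-based
#' integration), computes a PCA embedding (`dims` components), builds a
#' shared-nearest-neighbour graph (`k` neighbours) and detects
#' communities with Leiden at the given resolution. Cluster labels are
#' provisional (`C1`, `C2`, ...) until [annotateSubtypes()] is applied.
#'
#' The stored `embedding` is the reference expression pushed through the
#' global scaling statistics and the loadings - the exact pipeline
#' [projectCells()] applies to a query - so self-projection reproduces it
#' to numerical precision. Clustering uses the batch-corrected scores.
#'
#' @param counts SingleCellExperiment (with `sample` colData used as
#'   batch) or count matrix.
#' @param panel character vector of panel genes (subset of rownames).
#' @param dims number of embedding dimensions (default 20).
#' @param k neighbours for the SNN graph (default 10).
#' @param resolution Leiden resolution (default 0.4).
#' @param seed RNG seed.
#' @param batch optional explicit batch label per cell.
#' @return a [ReferenceMap-class].
#' @export
buildReference <- function(counts, panel, dims = 20, k = 10,
                           resolution = 0.4, seed = 42, batch = NULL) {
  m <- .getCounts(counts)
  if (!all(panel %in% rownames(m))) {
    stop("panel contains genes absent from the count matrix")
  }
  if (ncol(m) <= dims) stop("fewer cells than embedding dimensions")
  if (dims >= length(panel)) stop("dims must be smaller than the panel size")
  if (is.null(batch)) batch <- .getSamples(counts)
  set.seed(.checkSeed(seed))

  logn <- as.matrix(logNormalize(m))
  lp <- logn[panel, , drop = FALSE]
  x_corr <- .batchStandardize(lp, batch)

  pca <- stats::prcomp(t(x_corr), rank. = dims, center = FALSE, scale. = FALSE)
  loadings <- pca$rotation[, seq_len(dims), drop = FALSE]
  corr_scores <- pca$x[, seq_len(dims), drop = FALSE]

  ## global scaling statistics define projection space
  g_mean <- rowMeans(lp)
  g_sd <- apply(lp, 1L, stats::sd)
  g_sd[g_sd == 0 | is.na(g_sd)] <- 1
  embedding <- crossprod((lp - g_mean) / g_sd, loadings)

  cl <- .snnCluster(corr_scores, k = k, resolution = resolution, seed = seed)
  labels <- factor(paste0("C", cl), levels = paste0("C", sort(unique(cl))))

  subtype_means <- vapply(levels(labels), function(l) {
    rowMeans(logn[, labels == l, drop = FALSE])
  }, numeric(nrow(logn)))
  prototypes <- t(subtype_means[panel, , drop = FALSE])

  methods::new("ReferenceMap",
    genePanel = panel,
    scaling = data.frame(gene = panel, mean = g_mean, sd = g_sd,
                         row.names = panel),
    loadings = loadings,
    embedding = embedding,
    correctedEmbedding = corr_scores,
    cluster = cl,
    subtype = labels,
    subtypeMeans = subtype_means,
    prototypes = prototypes,
    annotation = data.frame(),
    params = list(dims = dims, k = k, resolution = resolution, seed = seed,
                  scaleFactor = 1e4))
}

#' Annotate reference clusters with marker signatures
#'
#' Scores each marker signature per cell ([scoreSignature()]), averages
#' scores per cluster and assigns every cluster the subtype whose
#' signature scores highest; clusters mapping to the same subtype are
#' merged. Ties are broken by signature order (with a warning); calls
#' whose winning margin is below `marginFlag` are flagged low-margin in
#' the audit table.
#'
#' @param map a [ReferenceMap-class] from [buildReference()].
#' @param markerSignatures named list of gene sets, one per candidate
#'   subtype.
#' @param counts the reference counts the map was built from.
#' @param maxRank rank cutoff for signature scoring (default 1500).
#' @param marginFlag low-margin threshold on the score gap (default 0.05).
#' @return the map with `subtype` relabeled, `prototypes`/`subtypeMeans`
#'   recomputed per subtype, and the assignment audit in `@annotation`.
#' @export
annotateSubtypes <- function(map, markerSignatures, counts,
                             maxRank = 1500, marginFlag = 0.05) {
  m <- .getCounts(counts)
  if (ncol(m) != length(map@cluster)) {
    stop("counts must cover exactly the reference cells")
  }
  scores <- vapply(markerSignatures, function(g) {
    scoreSignature(m, g, maxRank = maxRank)
  }, numeric(ncol(m)))
  clusters <- paste0("C", map@cluster)
  cl_levels <- paste0("C", sort(unique(map@cluster)))
  cl_scores <- t(vapply(cl_levels, function(cl) {
    colMeans(scores[clusters == cl, , drop = FALSE])
  }, numeric(length(markerSignatures))))
  colnames(cl_scores) <- names(markerSignatures)

  best <- apply(cl_scores, 1L, function(v) {
    top <- which(v == max(v))
    if (length(top) > 1L) {
      warning("signature tie on a cluster; broken by signature order")
    }
    top[1L]
  })
  margin <- apply(cl_scores, 1L, function(v) {
    s <- sort(v, decreasing = TRUE)
    if (length(s) > 1L) s[1L] - s[2L] else s[1L]
  })
  assigned <- names(markerSignatures)[best]
  audit <- data.frame(cluster = cl_levels, subtype = assigned,
                      score = cl_scores[cbind(seq_along(best), best)],
                      margin = margin, low_margin = margin < marginFlag,
                      stringsAsFactors = FALSE)

  new_labels <- assigned[match(clusters, cl_levels)]
  lv <- names(markerSignatures)[names(markerSignatures) %in% new_labels]
  map@subtype <- factor(new_labels, levels = lv)
  logn <- as.matrix(logNormalize(m))
  subtype_means <- vapply(lv, function(l) {
    rowMeans(logn[, new_labels == l, drop = FALSE])
  }, numeric(nrow(logn)))
  map@subtypeMeans <- subtype_means
  map@prototypes <- t(subtype_means[map@genePanel, , drop = FALSE])
  map@annotation <- audit
  methods::validObject(map)
  map
}

#' Derive subtype marker signatures from the reference
#'
#' For each subtype, performs rank-sum (Wilcoxon) differential expression
#' against the other subtypes in the same state group (e.g. the three
#' effector subtypes against each other, the three memory subtypes
#' against each other) and keeps the top up-regulated genes. Ribosomal,
#' sex-specific and TCR transcripts are removed from the candidates.
#'
#' @param map an annotated [ReferenceMap-class].
#' @param counts the reference counts.
#' @param stateOf named character: state group per subtype (subtypes
#'   missing from `stateOf` are compared against all other subtypes).
#' @param nTop maximum genes per signature (default 50).
#' @param fdr BH-adjusted p-value cutoff (default 0.05).
#' @param minLogFC minimum log fold-change (default 0.25).
#' @return named list of character vectors.
#' @export
subtypeSignatures <- function(map, counts, stateOf = NULL, nTop = 50,
                              fdr = 0.05, minLogFC = 0.25) {
  m <- .getCounts(counts)
  logn <- as.matrix(logNormalize(m))
  labels <- as.character(map@subtype)
  bs <- builtinGeneSets(rownames(m))
  banned <- unique(unlist(bs[c("ribo", "sex", "tcr")], use.names = FALSE))
  candidates <- setdiff(rownames(m), banned)

  sigs <- list()
  for (st in levels(map@subtype)) {
    in_st <- labels == st
    if (sum(in_st) < 3L) {
      warning("subtype '", st, "' has fewer than 3 cells; skipped")
      next
    }
    group <- if (!is.null(stateOf) && st %in% names(stateOf)) {
      others <- names(stateOf)[stateOf == stateOf[[st]]]
      setdiff(others, st)
    } else {
      setdiff(levels(map@subtype), st)
    }
    in_bg <- labels %in% group
    if (!any(in_bg)) {
      warning("no comparison cells for subtype '", st, "'; skipped")
      next
    }
    de <- .wilcoxDE(logn[candidates, in_st, drop = FALSE],
                    logn[candidates, in_bg, drop = FALSE])
    up <- de[de$padj < fdr & de$logFC > minLogFC, , drop = FALSE]
    if (nrow(up) == 0L) {
      warning("no discriminant genes for subtype '", st, "'")
      sigs[[st]] <- character(0)
    } else {
      up <- up[order(up$p), , drop = FALSE]
      sigs[[st]] <- head(rownames(up), nTop)
    }
  }
  sigs
}

## two-sided Wilcoxon rank-sum per gene between two log-normalized blocks
.wilcoxDE <- function(a, b) {
  p <- vapply(seq_len(nrow(a)), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (length(unique(c(x, y))) == 1L) return(1)
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  }, 0)
  lfc <- rowMeans(a) - rowMeans(b)
  data.frame(p = p, padj = stats::p.adjust(p, "BH"), logFC = lfc,
             row.names = rownames(a))
}
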