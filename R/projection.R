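## Projection of query cells into a ReferenceMap, kNN subtype
## classification, and diagnostics for reference-query correspondence and
## novel states.

#' Project query cells into a reference map
#'
#' Log-normalizes the query, standardizes panel genes with the
#' reference's scaling statistics and multiplies into the reference
#' loadings. Panel genes absent from the query are imputed as 0 after
#' standardization (i.e. at the reference mean). Matching is by gene
#' name, so file order is irrelevant.
#'
#' @param query SingleCellExperiment or count matrix.
#' @param ref a [ReferenceMap-class].
#' @return query cell x dimension embedding matrix.
#' @export
projectCells <- function(query, ref) {
  m <- .getCounts(query)
  shared <- intersect(ref@genePanel, rownames(m))
  overlap <- length(shared) / length(ref@genePanel)
  if (overlap < 0.1) {
    stop("query shares only ", round(100 * overlap, 1),
         "% of the reference gene panel (<10%)")
  }
  if (overlap < 0.5) {
    warning("query shares only ", round(100 * overlap, 1),
            "% of the reference gene panel")
  }
  logn <- as.matrix(logNormalize(m, scaleFactor = ref@params$scaleFactor))
  z <- matrix(0, nrow = length(ref@genePanel), ncol = ncol(m),
              dimnames = list(ref@genePanel, colnames(m)))
  sc <- ref@scaling[shared, ]
  z[shared, ] <- (logn[shared, , drop = FALSE] - sc$mean) / sc$sd
  crossprod(z, ref@loadings)
}

#' Classify projected cells by k-nearest-neighbour label transfer
#'
#' Majority vote of the `k` nearest reference cells (Euclidean distance
#' in the embedding space); ties are broken by the summed inverse
#' distance of the tied labels' neighbours. Confidence is the fraction
#' of the k neighbours carrying the winning label.
#'
#' @param embedding query embedding from [projectCells()].
#' @param ref a [ReferenceMap-class].
#' @param k neighbours (default 20; clamped with a warning if it exceeds
#'   the reference size).
#' @return a [ProjectionResult-class].
#' @export
classifySubtypes <- function(embedding, ref, k = 20) {
  if (k < 1) stop("k must be >= 1")
  n_ref <- nrow(ref@embedding)
  if (k > n_ref) {
    warning("k = ", k, " exceeds reference size; clamped to ", n_ref)
    k <- n_ref
  }
  nn <- BiocNeighbors::queryKNN(ref@embedding, embedding, k = k)
  labels <- as.character(ref@subtype)
  lv <- levels(ref@subtype)
  predicted <- character(nrow(embedding))
  confidence <- numeric(nrow(embedding))
  for (i in seq_len(nrow(embedding))) {
    lab <- labels[nn$index[i, ]]
    tab <- table(lab)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      w <- vapply(top, function(l) {
        d <- nn$distance[i, lab == l]
        sum(1 / pmax(d, .Machine$double.eps))
      }, 0)
      top <- top[which.max(w)]
    }
    predicted[i] <- top[1L]
    confidence[i] <- max(tab) / k
  }
  predicted <- factor(predicted, levels = lv)
  comp <- table(predicted) / length(predicted)
  methods::new("ProjectionResult",
    embedding = embedding, predicted = predicted, confidence = confidence,
    composition = setNames(as.numeric(comp), names(comp)), k = as.integer(k))
}

#' Marker profiles of query vs reference per predicted subtype
#'
#' For each predicted subtype present in the query, reports the mean
#' log-normalized expression of each panel gene side by side for query
#' and reference (the per-subtype reference means stored in the map).
#' Subtypes with no query cells are omitted; panel genes absent from the
#' query are reported as 0 and flagged.
#'
#' @param query SingleCellExperiment or count matrix.
#' @param result a [ProjectionResult-class] for these query cells.
#' @param ref a [ReferenceMap-class].
#' @param panel marker genes to profile.
#' @return long data.frame: `subtype`, `gene`, `query_mean`, `ref_mean`,
#'   `missing_in_query`.
#' @export
subtypeProfile <- function(query, result, ref, panel) {
  m <- .getCounts(query)
  logn <- as.matrix(logNormalize(m, scaleFactor = ref@params$scaleFactor))
  pred <- result@predicted
  out <- list()
  for (st in levels(pred)) {
    cols <- which(pred == st)
    if (length(cols) == 0L) next
    q_mean <- vapply(panel, function(g) {
      if (g %in% rownames(logn)) mean(logn[g, cols]) else 0
    }, 0)
    r_mean <- vapply(panel, function(g) {
      if (g %in% rownames(ref@subtypeMeans) && st %in% colnames(ref@subtypeMeans)) {
        ref@subtypeMeans[g, st]
      } else {
        0
      }
    }, 0)
    out[[st]] <- data.frame(subtype = st, gene = panel,
                            query_mean = q_mean, ref_mean = r_mean,
                            missing_in_query = !(panel %in% rownames(logn)),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Average silhouette coefficient per subtype for projected cells
#'
#' For each query cell, cohesion `a` is its mean distance to the
#' reference cells of its assigned subtype and separation `b` the
#' smallest mean distance to any other reference subtype; the silhouette
#' is `(b - a)/max(a, b)`. Coefficients are averaged per subtype.
#' Subtypes with a single query cell are reported as `NA`.
#'
#' @param result a [ProjectionResult-class].
#' @param ref a [ReferenceMap-class] (needs >= 2 subtypes).
#' @return named numeric vector of per-subtype mean silhouettes.
#' @export
silhouetteBySubtype <- function(result, ref) {
  lv <- levels(ref@subtype)
  if (length(lv) < 2L) stop("silhouette requires at least 2 subtypes")
  d2 <- .crossDist2(result@embedding, ref@embedding)
  d <- sqrt(d2)
  mean_to <- vapply(lv, function(l) {
    rowMeans(d[, ref@subtype == l, drop = FALSE])
  }, numeric(nrow(d)))
  if (nrow(d) == 1L) mean_to <- matrix(mean_to, nrow = 1L,
                                       dimnames = list(NULL, lv))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- as.character(result@predicted[i])
    a <- mean_to[i, own]
    b <- min(mean_to[i, setdiff(lv, own)])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  out <- setNames(rep(NA_real_, length(lv)), lv)
  for (l in lv) {
    idx <- which(result@predicted == l)
    if (length(idx) >= 2L) out[l] <- mean(sil[idx])
    ## single query cell: reported as missing
  }
  out
}

#' Differential expression between reference and query within a subtype
#'
#' Two-sided Wilcoxon rank-sum per gene on log-normalized expression,
#' with log fold-change (query minus reference) and Benjamini-Hochberg
#' FDR.
#'
#' @param query query SingleCellExperiment or count matrix.
#' @param result a [ProjectionResult-class] for the query.
#' @param refCounts reference counts aligned with the map's cells.
#' @param ref a [ReferenceMap-class].
#' @param subtype subtype label to test (needs >= 3 cells on both sides).
#' @return data.frame with `p`, `padj`, `logFC` per shared gene, ordered
#'   by p-value.
#' @export
discriminantGenes <- function(query, result, refCounts, ref, subtype) {
  qm <- .getCounts(query)
  rm_ <- .getCounts(refCounts)
  q_cols <- which(result@predicted == subtype)
  ## align reference cells by name so refCounts may be a subset of the map
  ref_cells <- rownames(ref@embedding)
  r_labels <- if (!is.null(colnames(rm_)) && !is.null(ref_cells) &&
                  all(colnames(rm_) %in% ref_cells)) {
    as.character(ref@subtype)[match(colnames(rm_), ref_cells)]
  } else {
    if (ncol(rm_) != length(ref@subtype)) {
      stop("refCounts must cover the map's cells or carry matching cell names")
    }
    as.character(ref@subtype)
  }
  r_cols <- which(r_labels == subtype)
  if (length(q_cols) < 3L) stop("fewer than 3 query cells in subtype '",
                                subtype, "'")
  if (length(r_cols) < 3L) stop("fewer than 3 reference cells in subtype '",
                                subtype, "'")
  shared <- intersect(rownames(qm), rownames(rm_))
  q_logn <- as.matrix(logNormalize(qm[shared, q_cols, drop = FALSE]))
  r_logn <- as.matrix(logNormalize(rm_[, r_cols, drop = FALSE]))[shared, ,
                                                                 drop = FALSE]
  de <- .wilcoxDE(q_logn, r_logn)
  de[order(de$p), ]
}

#' Joint re-embedding of reference and query to expose novel states
#'
#' Recomputes a joint embedding (global standardization of the shared
#' panel, PCA, SNN graph, Leiden communities) of reference plus query
#' cells, then flags communities whose reference membership is below
#' `novelThreshold` as putative novel states absent from the reference.
#' The first two principal components serve as 2-D display coordinates.
#'
#' @param ref a [ReferenceMap-class].
#' @param refCounts reference counts aligned with the map.
#' @param query query counts (may have zero cells).
#' @param dims,k,resolution,seed graph/embedding parameters (defaults
#'   follow the map's build parameters).
#' @param novelThreshold maximum reference fraction for a cluster to be
#'   called novel (default 0.25).
#' @return list: `coords` (cell x 2 matrix), `cluster` (integer),
#'   `is_query` (logical), `novel_clusters` (integer vector of flagged
#'   communities), `cluster_ref_fraction`.
#' @export
recalculateEmbedding <- function(ref, refCounts, query, dims = NULL,
                                 k = NULL, resolution = NULL, seed = 42,
                                 novelThreshold = 0.25) {
  dims <- dims %||% ref@params$dims
  k <- k %||% ref@params$k
  resolution <- resolution %||% ref@params$resolution
  rm_ <- .getCounts(refCounts)
  qm <- if (is.null(query)) NULL else .getCounts(query)
  n_query <- if (is.null(qm)) 0L else ncol(qm)

  panel <- if (n_query) {
    intersect(ref@genePanel, rownames(qm))
  } else {
    ref@genePanel
  }
  joint <- cbind(as.matrix(logNormalize(rm_))[panel, , drop = FALSE],
                 if (n_query) {
                   as.matrix(logNormalize(qm))[panel, , drop = FALSE]
                 })
  mu <- rowMeans(joint)
  sdv <- apply(joint, 1L, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  x <- (joint - mu) / sdv
  set.seed(.checkSeed(seed))
  dims <- min(dims, nrow(x) - 1L, ncol(x) - 1L)
  pca <- stats::prcomp(t(x), rank. = dims, center = FALSE, scale. = FALSE)
  scores <- pca$x[, seq_len(dims), drop = FALSE]
  cl <- .snnCluster(scores, k = k, resolution = resolution,
                    seed = .checkSeed(seed))
  is_query <- c(rep(FALSE, ncol(rm_)), rep(TRUE, n_query))
  ref_frac <- vapply(sort(unique(cl)), function(g) {
    mean(!is_query[cl == g])
  }, 0)
  names(ref_frac) <- sort(unique(cl))
  novel <- as.integer(names(ref_frac)[ref_frac < novelThreshold])
  list(coords = scores[, 1:2, drop = FALSE], cluster = cl,
       is_query = is_query, novel_clusters = novel,
       cluster_ref_fraction = ref_frac)
}
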