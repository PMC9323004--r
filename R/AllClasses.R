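## S4 classes for the central objects: the synthetic cohort specification,
## the reference map, and projection results.

#' CohortSpec: parameters of a synthetic paired-expression/TCR cohort
#'
#' Describes the statistical structure of a multi-sample cohort of T cells
#' with paired transcriptomes and TCR chains: subtype composition, marker
#' programs, negative-binomial counts, a clone-size law putting roughly
#' half of the clonal space in large clones, and an optional fraction of
#' planted fate-biased clonotypes. Created by [cohortSpec()].
#'
#' @slot nSamples number of samples ("animals").
#' @slot cellsPerSample target cells per sample.
#' @slot subtypes ordered subtype labels.
#' @slot background per-subtype background frequencies (sums to 1).
#' @slot nGenes size of the gene universe (markers + housekeeping +
#'   mitochondrial/ribosomal/cycling genes).
#' @slot nMarkerGenes marker genes per subtype.
#' @slot markerLogFC natural-log fold elevation of marker means in their
#'   subtype.
#' @slot baselineMean mean UMI per gene per cell for non-marker genes.
#' @slot dispersion negative-binomial overdispersion (size = 1/dispersion).
#' @slot cloneSizeLaw list describing the clone-size distribution; see
#'   [cohortSpec()].
#' @slot biasedFraction fraction of expanded clonotypes planted with bias.
#' @slot plantedBias target bias statistic c for planted clones.
#' @slot sharedClones list of character vectors of sample names; each
#'   element is one clonotype planted in all listed samples.
#' @slot qcViolationRate fraction of cells per QC rule emitted by
#'   [generateQCStressCells()].
#' @slot cyclingFraction fraction of cells given a cell-cycle program.
#' @slot doubletRate fraction of cells emitted with two alpha chains.
#' @slot seed RNG seed.
#' @export
setClass("CohortSpec", representation(
  nSamples = "integer", cellsPerSample = "integer",
  subtypes = "character", background = "numeric",
  nGenes = "integer", nMarkerGenes = "integer",
  markerLogFC = "numeric", baselineMean = "numeric", dispersion = "numeric",
  cloneSizeLaw = "list", biasedFraction = "numeric", plantedBias = "numeric",
  sharedClones = "list", qcViolationRate = "numeric",
  cyclingFraction = "numeric", doubletRate = "numeric", seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (length(object@background) != length(object@subtypes))
    msg <- c(msg, "background must have one frequency per subtype")
  if (abs(sum(object@background) - 1) > 1e-8)
    msg <- c(msg, "background frequencies must sum to 1")
  if (any(object@background < 0))
    msg <- c(msg, "background frequencies must be nonnegative")
  if (object@biasedFraction < 0 || object@biasedFraction > 1)
    msg <- c(msg, "biasedFraction must be in [0, 1]")
  if (object@plantedBias < 0 || object@plantedBias > 1)
    msg <- c(msg, "plantedBias must be in [0, 1]")
  if (anyDuplicated(object@subtypes))
    msg <- c(msg, "subtype labels must be unique")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSamples, "samples x ~", object@cellsPerSample,
      "cells,", length(object@subtypes), "subtypes,",
      object@nGenes, "genes\n")
  cat("  biased fraction:", object@biasedFraction,
      " planted bias:", object@plantedBias,
      " seed:", object@seed, "\n")
})

#' ReferenceMap: a simplified single-cell reference atlas
#'
#' Holds the gene panel, scaling statistics, PCA loadings and cell
#' coordinates of a reference map, together with per-cell subtype labels,
#' per-subtype mean expression profiles and clustering metadata. Built by
#' [buildReference()] and annotated by [annotateSubtypes()].
#'
#' The stored `embedding` is the reference expression pushed through the
#' same pipeline a query follows (global scaling then loadings), so
#' projecting the reference onto itself reproduces it exactly. Clustering
#' is performed on batch-corrected scores kept in `correctedEmbedding`.
#'
#' @slot genePanel variable genes used for the map.
#' @slot scaling data.frame with per-gene `mean` and `sd` of log-normalized
#'   expression over the reference (projection scaling statistics).
#' @slot loadings gene x dimension orthonormal projection matrix.
#' @slot embedding cell x dimension coordinates in projection space.
#' @slot correctedEmbedding cell x dimension batch-corrected PCA scores.
#' @slot cluster integer cluster per cell (graph community).
#' @slot subtype factor of subtype labels per cell.
#' @slot subtypeMeans gene x subtype matrix of mean log-normalized
#'   expression (all genes; used for marker profiles).
#' @slot prototypes subtype x panel-gene matrix of mean expression.
#' @slot annotation data.frame audit table of cluster -> subtype calls.
#' @slot params list of build parameters (dims, k, resolution, seed,
#'   normalization scale factor).
#' @export
setClass("ReferenceMap", representation(
  genePanel = "character", scaling = "data.frame",
  loadings = "matrix", embedding = "matrix",
  correctedEmbedding = "matrix", cluster = "integer",
  subtype = "factor", subtypeMeans = "matrix",
  prototypes = "matrix", annotation = "data.frame", params = "list"
))

setValidity("ReferenceMap", function(object) {
  msg <- character(0)
  if (nrow(object@loadings) != length(object@genePanel))
    msg <- c(msg, "loadings rows must match gene panel")
  cp <- crossprod(object@loadings)
  if (max(abs(cp - diag(ncol(object@loadings)))) > 1e-6)
    msg <- c(msg, "loadings columns must be orthonormal")
  if (nrow(object@embedding) != length(object@subtype))
    msg <- c(msg, "every reference cell must carry a subtype label")
  if (anyNA(object@subtype))
    msg <- c(msg, "subtype labels must not be NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceMap", function(object) {
  cat("ReferenceMap:", nrow(object@embedding), "cells,",
      length(object@genePanel), "panel genes,",
      ncol(object@embedding), "dims\n")
  cat("  subtypes:", paste(levels(object@subtype), collapse = ", "), "\n")
  comp <- table(object@subtype)
  print(comp)
})

#' @describeIn ReferenceMap variable genes of the map.
#' @param x a `ReferenceMap`.
#' @export
genePanel <- function(x) x@genePanel

#' @describeIn ReferenceMap cell x dimension reference coordinates.
#' @export
refEmbedding <- function(x) x@embedding

#' @describeIn ReferenceMap per-cell subtype labels.
#' @export
subtypeLabels <- function(x) x@subtype

#' @describeIn ReferenceMap gene x dimension loading matrix.
#' @export
refLoadings <- function(x) x@loadings

#' ProjectionResult: query cells classified in a reference map
#'
#' @slot embedding query cell x dimension coordinates in reference space.
#' @slot predicted factor of predicted subtype per query cell.
#' @slot confidence fraction of the k nearest reference neighbours that
#'   agree with the predicted label.
#' @slot composition named numeric; fraction of query cells per subtype
#'   (sums to 1).
#' @slot k number of neighbours used.
#' @export
setClass("ProjectionResult", representation(
  embedding = "matrix", predicted = "factor", confidence = "numeric",
  composition = "numeric", k = "integer"
))

setValidity("ProjectionResult", function(object) {
  msg <- character(0)
  if (length(object@predicted) != nrow(object@embedding))
    msg <- c(msg, "one predicted label per embedded cell required")
  if (any(object@confidence < 0 | object@confidence > 1))
    msg <- c(msg, "confidence must be in [0, 1]")
  if (length(object@composition) &&
      abs(sum(object@composition) - 1) > 1e-8)
    msg <- c(msg, "composition must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProjectionResult", function(object) {
  cat("ProjectionResult:", nrow(object@embedding), "query cells, k =",
      object@k, "\n")
  print(round(object@composition, 3))
})

#' @describeIn ProjectionResult predicted subtype per query cell.
#' @param x a `ProjectionResult`.
#' @export
predictedSubtype <- function(x) x@predicted

#' @describeIn ProjectionResult query coordinates in reference space.
#' @export
queryEmbedding <- function(x) x@embedding

#' @describeIn ProjectionResult neighbour agreement per query cell.
#' @export
classificationConfidence <- function(x) x@confidence

#' @describeIn ProjectionResult subtype composition of the query.
#' @export
subtypeComposition <- function(x) x@composition
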