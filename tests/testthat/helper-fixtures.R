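# Shared fixtures, built once per test run. The reference cohort uses six
# well-separated major subtypes at realistic per-cell sequencing depth
# (~3500 UMIs/cell) with marker log-fold elevation 1.

.fx <- new.env(parent = emptyenv())

majorSubtypes <- function() {
  list(subtypes = c("Th1_Effector", "Tfh_Effector", "Tcmp",
                    "Th1_Memory", "Tfh_Memory", "Tcm"),
       background = c(0.25, 0.22, 0.18, 0.13, 0.12, 0.10))
}

refCohortSpec <- function(seed = 7, nSamples = 2, cellsPerSample = 600) {
  mj <- majorSubtypes()
  cohortSpec(nSamples = nSamples, cellsPerSample = cellsPerSample,
             subtypes = mj$subtypes, background = mj$background,
             nGenes = 300, nMarkerGenes = 20, markerLogFC = 1,
             baselineMean = 5, biasedFraction = 0, seed = seed)
}

# annotated reference built from a 2-sample, 1200-cell cohort
refFixture <- function() {
  if (!is.null(.fx$ref)) return(.fx$ref)
  co <- generateCohort(refCohortSpec())
  sce <- combineSamples(co)
  panel <- selectVariableGenes(sce, n = 150)
  map <- buildReference(sce, panel, dims = 20, k = 10, resolution = 0.4,
                        seed = 3)
  sigs <- cohortMarkerSets(co)[majorSubtypes()$subtypes]
  map <- annotateSubtypes(map, sigs, sce, maxRank = 150)
  .fx$ref <- list(cohort = co, sce = sce, panel = panel, map = map,
                  sigs = sigs,
                  truth = co$truth$subtype_of_cell[colnames(sce)])
  .fx$ref
}

# independent query drawn from the same subtype programs
queryFixture <- function() {
  if (!is.null(.fx$query)) return(.fx$query)
  mj <- majorSubtypes()
  co <- cohortSpec(nSamples = 1, cellsPerSample = 300,
                   subtypes = mj$subtypes, background = mj$background,
                   nGenes = 300, nMarkerGenes = 20, markerLogFC = 1,
                   baselineMean = 5, biasedFraction = 0, seed = 99)
  coq <- generateCohort(co)
  .fx$query <- list(cohort = coq, sce = combineSamples(coq),
                    truth = coq$truth$subtype_of_cell)
  .fx$query
}

# independent adjusted Rand index (oracle for clustering recovery)
ariOracle <- function(a, b) mclust::adjustedRandIndex(a, b)

# exact multinomial enumeration of the bias-statistic null for a clone of
# size s over the label frequencies q (independent oracle for the
# permutation null)
enumBiasNull <- function(s, q) {
  k <- length(q)
  grid <- expand.grid(rep(list(0:s), k))
  grid <- grid[rowSums(grid) == s, , drop = FALSE]
  pr <- apply(grid, 1L, function(x) dmultinom(x, prob = q))
  cv <- apply(grid, 1L, function(x) max(0, max((x / s - q) / (1 - q))))
  list(mean = sum(pr * cv), sd = sqrt(sum(pr * cv^2) - sum(pr * cv)^2))
}

# tiny hand-rolled ReferenceMap in a 2-D identity space, for geometric
# edge cases of classification and silhouettes
toyMap <- function(refCoords, subtypes) {
  genes <- c("g1", "g2")
  new("ReferenceMap",
      genePanel = genes,
      scaling = data.frame(gene = genes, mean = c(0, 0), sd = c(1, 1),
                           row.names = genes),
      loadings = diag(2),
      embedding = refCoords,
      correctedEmbedding = refCoords,
      cluster = as.integer(factor(subtypes)),
      subtype = factor(subtypes),
      subtypeMeans = matrix(0, 2, length(unique(subtypes)),
                            dimnames = list(genes, unique(subtypes))),
      prototypes = matrix(0, length(unique(subtypes)), 2,
                          dimnames = list(unique(subtypes), genes)),
      annotation = data.frame(),
      params = list(dims = 2, k = 1, resolution = 0.4, seed = 1,
                    scaleFactor = 1e4))
}
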