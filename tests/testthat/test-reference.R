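test_that("per-condition cap downsamples uniformly and reproducibly", {
  co <- generateCohort(refCohortSpec(seed = 41, nSamples = 2,
                                     cellsPerSample = 80))
  sce <- combineSamples(co)
  capped <- capPerCondition(sce, "sample", cap = 50, seed = 4)
  expect_equal(unname(table(colData(capped)$sample)),
               unname(pmin(table(colData(sce)$sample), 50)),
               ignore_attr = TRUE)
  capped2 <- capPerCondition(sce, "sample", cap = 50, seed = 4)
  expect_identical(colnames(capped), colnames(capped2))
  # groups under the cap are kept whole
  small <- capPerCondition(sce, "sample", cap = 5000, seed = 4)
  expect_equal(ncol(small), ncol(sce))
})

test_that("variable-gene selection respects exclusions and panel size", {
  fx <- refFixture()
  expect_length(fx$panel, 150)
  # built-in exclusions keep mito/ribo/cycling/TCR genes out
  bs <- builtinGeneSets(rownames(fx$sce))
  expect_length(intersect(fx$panel, unlist(bs[c("mito", "ribo", "cycling")])),
                0)
  # excluding the top-ranked gene removes it from the panel
  top <- fx$panel[1]
  panel2 <- selectVariableGenes(fx$sce, n = 149,
                                exclusionSets = list(custom = top))
  expect_false(top %in% panel2)
  # asking for more genes than remain eligible fails loudly
  expect_error(
    selectVariableGenes(fx$sce, n = nrow(fx$sce),
                        exclusionSets = list(all = rownames(fx$sce)[1:10])),
    "eligible")
})

test_that("reference clustering recovers the planted subtypes", {
  fx <- refFixture()
  cl <- fx$map@cluster
  expect_gte(length(unique(cl)), 6)
  expect_gte(ariOracle(cl, fx$truth), 0.8)
})

test_that("the reference build is deterministic given the seed", {
  fx <- refFixture()
  map2 <- buildReference(fx$sce, fx$panel, dims = 20, k = 10,
                         resolution = 0.4, seed = 3)
  expect_identical(refEmbedding(map2), refEmbedding(fx$map))
  expect_identical(map2@cluster, fx$map@cluster)
})

test_that("a single-subtype cohort collapses to one dominant cluster", {
  spec <- cohortSpec(nSamples = 1, cellsPerSample = 250, subtypes = "Th1",
                     background = 1, nGenes = 300, nMarkerGenes = 20,
                     baselineMean = 5, biasedFraction = 0, seed = 19)
  sce <- combineSamples(generateCohort(spec))
  panel <- selectVariableGenes(sce, n = 100)
  map <- buildReference(sce, panel, dims = 20, seed = 2)
  expect_gte(max(table(map@cluster)) / ncol(sce), 0.9)
})

test_that("signature scores hit their extreme values and null expectation", {
  # cell 1: signature occupies the top ranks; cell 2: signature unexpressed
  # and beyond the rank cutoff
  g <- 200
  m <- matrix(1, nrow = g, ncol = 2,
              dimnames = list(paste0("g", seq_len(g)), c("top", "none")))
  sig <- paste0("g", 1:5)
  m[sig, 1] <- 100:104
  m[sig, 2] <- 0
  m[, 2][m[, 2] == 1] <- 2   # non-signature genes expressed
  expect_equal(unname(scoreSignature(m, sig, maxRank = 50)["top"]), 1)
  expect_equal(unname(scoreSignature(m, sig, maxRank = 50)["none"]), 0)

  # random signature on exchangeable data scores ~0.5 on average
  set.seed(8)
  r <- matrix(rpois(g * 400, 5), nrow = g,
              dimnames = list(paste0("g", seq_len(g)), NULL))
  sig <- sample(rownames(r), 10)
  sc <- scoreSignature(r, sig, maxRank = g)
  n <- length(sig)
  expected <- 1 - (n * (g + 1) / 2 - n * (n + 1) / 2) /
    (n * (g + 1) - n * (n + 1) / 2)
  expect_lt(abs(mean(sc) - expected), 3 * sd(sc) / sqrt(length(sc)) + 1e-6)
  expect_true(all(sc >= 0 & sc <= 1))

  expect_warning(z <- scoreSignature(r, c("absent1", "absent2")), "no genes")
  expect_true(all(z == 0))
})

test_that("signature-guided annotation labels planted programs correctly", {
  fx <- refFixture()
  acc <- mean(as.character(subtypeLabels(fx$map)) == fx$truth)
  expect_gte(acc, 0.9)
  expect_true(all(levels(subtypeLabels(fx$map)) %in% majorSubtypes()$subtypes))
  expect_true(all(c("cluster", "subtype", "score", "margin") %in%
                    colnames(fx$map@annotation)))
})

test_that("clusters sharing a winning signature are merged under one label", {
  fx <- refFixture()
  th1 <- fx$sigs$Th1_Effector
  rest <- unique(unlist(fx$sigs[names(fx$sigs) != "Th1_Effector"]))
  map2 <- annotateSubtypes(fx$map, list(Th1 = th1, Rest = rest), fx$sce,
                           maxRank = 150)
  expect_lte(nlevels(subtypeLabels(map2)), 2)
  expect_gt(sum(map2@annotation$subtype == "Rest"), 1)  # merged clusters
})

test_that("tied signatures warn and fall back to signature order", {
  fx <- refFixture()
  sig <- fx$sigs$Th1_Effector
  expect_warning(
    map2 <- annotateSubtypes(fx$map, list(first = sig, second = sig),
                             fx$sce, maxRank = 150),
    "tie")
  expect_identical(unique(map2@annotation$subtype), "first")
})

test_that("derived subtype signatures recover planted markers and stay clean", {
  fx <- refFixture()
  sigs <- subtypeSignatures(fx$map, fx$sce, nTop = 30)
  planted <- cohortMarkerSets(fx$cohort)
  for (st in names(sigs)) {
    hits <- length(intersect(sigs[[st]], planted[[st]]))
    expect_gte(hits, 10)
  }
  all_sig <- unlist(sigs)
  bs <- builtinGeneSets(rownames(fx$sce))
  expect_length(intersect(all_sig, c(bs$ribo, bs$tcr, bs$sex)), 0)
})

test_that("TCR-segment genes are excluded from signatures even when they discriminate", {
  fx <- refFixture()
  sce2 <- fx$sce
  m <- counts(sce2)
  trbv <- as(Matrix::Matrix(0, 1, ncol(m), sparse = TRUE), "CsparseMatrix")
  rownames(trbv) <- "Trbv5"
  trbv[1, as.character(subtypeLabels(fx$map)) == "Tcm"] <- 50
  m2 <- rbind(m, trbv)
  sce2 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m2),
    colData = colData(fx$sce))
  sigs <- subtypeSignatures(fx$map, sce2, nTop = 30)
  expect_false("Trbv5" %in% unlist(sigs))
})

test_that("indistinguishable subtypes yield empty signatures with a warning", {
  spec <- cohortSpec(nSamples = 1, cellsPerSample = 120, subtypes = "X",
                     background = 1, nGenes = 300, nMarkerGenes = 5,
                     baselineMean = 5, biasedFraction = 0, seed = 27)
  sce <- combineSamples(generateCohort(spec))
  map <- buildReference(sce, selectVariableGenes(sce, 80), dims = 10,
                        seed = 2)
  # force two labels onto homogeneous cells
  map@subtype <- factor(rep(c("A", "B"), length.out = ncol(sce)))
  expect_warning(sigs <- subtypeSignatures(map, sce), "no discriminant")
  expect_true(all(lengths(sigs) == 0))
})

test_that("a saved reference map reloads identically", {
  fx <- refFixture()
  dir <- withr::local_tempdir()
  saveReferenceMap(fx$map, dir)
  back <- loadReferenceMap(dir)
  expect_equal(refEmbedding(back), refEmbedding(fx$map))
  expect_equal(refLoadings(back), refLoadings(fx$map))
  expect_identical(as.character(subtypeLabels(back)),
                   as.character(subtypeLabels(fx$map)))
  expect_equal(back@scaling$mean, fx$map@scaling$mean)
  # a reloaded map projects queries identically
  q <- queryFixture()
  expect_equal(projectCells(q$sce, back), projectCells(q$sce, fx$map))
})
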