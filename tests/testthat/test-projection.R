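test_that("self-projection reproduces the reference embedding", {
  fx <- refFixture()
  emb <- projectCells(fx$sce, fx$map)
  expect_lt(max(abs(emb - refEmbedding(fx$map))), 1e-8)
})

test_that("projection is invariant to gene order and rejects disjoint panels", {
  fx <- refFixture()
  emb <- projectCells(fx$sce, fx$map)
  shuffled <- fx$sce[sample(nrow(fx$sce)), ]
  expect_equal(projectCells(shuffled, fx$map), emb)

  renamed <- counts(fx$sce)
  rownames(renamed) <- paste0("other_", rownames(renamed))
  expect_error(projectCells(renamed, fx$map), "10%")
})

test_that("self-classification at k = 1 returns the map's own labels", {
  fx <- refFixture()
  emb <- projectCells(fx$sce, fx$map)
  res <- classifySubtypes(emb, fx$map, k = 1)
  expect_identical(as.character(predictedSubtype(res)),
                   as.character(subtypeLabels(fx$map)))
  expect_true(all(classificationConfidence(res) == 1))
})

test_that("queries from reference programs classify correctly", {
  fx <- refFixture()
  q <- queryFixture()
  res <- classifySubtypes(projectCells(q$sce, fx$map), fx$map, k = 20)
  acc <- mean(as.character(predictedSubtype(res)) == q$truth[colnames(q$sce)])
  expect_gte(acc, 0.9)
  expect_equal(sum(subtypeComposition(res)), 1)
})

test_that("balanced ties resolve deterministically by inverse distance", {
  map <- toyMap(rbind(c(-1, 0), c(1, 0)), c("A", "B"))
  q <- rbind(c(0, 0))
  r1 <- classifySubtypes(q, map, k = 2)
  r2 <- classifySubtypes(q, map, k = 2)
  expect_identical(as.character(predictedSubtype(r1)),
                   as.character(predictedSubtype(r2)))
  expect_equal(classificationConfidence(r1), 0.5)
  # an asymmetric query resolves toward the nearer subtype
  r3 <- classifySubtypes(rbind(c(-0.2, 0)), map, k = 2)
  expect_identical(as.character(predictedSubtype(r3)), "A")
  expect_warning(classifySubtypes(q, map, k = 5), "clamped")
})

test_that("marker profiles match the reference on self-queries", {
  fx <- refFixture()
  emb <- projectCells(fx$sce, fx$map)
  res <- classifySubtypes(emb, fx$map, k = 1)  # predicted == map labels
  panel <- c("Cxcr6", "Cxcr5", "Ccr7", "Tcf7", "Il7r", "NotAGene")
  prof <- subtypeProfile(fx$sce, res, fx$map, panel)
  real <- prof[!prof$missing_in_query, ]
  expect_equal(real$query_mean, real$ref_mean, tolerance = 1e-10)
  expect_true(all(prof$missing_in_query[prof$gene == "NotAGene"]))
  expect_true(all(prof$query_mean[prof$gene == "NotAGene"] == 0))
  # subtypes absent from the query are omitted
  sub <- res
  sub@predicted <- factor(rep("Tcm", nrow(emb)),
                          levels = levels(res@predicted))
  prof2 <- subtypeProfile(fx$sce, sub, fx$map, panel)
  expect_identical(unique(prof2$subtype), "Tcm")
})

test_that("silhouettes are positive for matching queries and expose misassignment", {
  fx <- refFixture()
  q <- queryFixture()
  res <- classifySubtypes(projectCells(q$sce, fx$map), fx$map, k = 20)
  sil <- silhouetteBySubtype(res, fx$map)
  present <- names(which(table(predictedSubtype(res)) >= 2))
  expect_true(all(sil[present] > 0))

  # a query at the midpoint of two cluster centroids sits near zero
  map <- toyMap(rbind(c(-1, 0), c(-1, 0.1), c(1, 0), c(1, 0.1)),
                c("A", "A", "B", "B"))
  mid <- methods::new("ProjectionResult",
                      embedding = rbind(c(0, 0.05), c(0, 0.051)),
                      predicted = factor(c("A", "A"), c("A", "B")),
                      confidence = c(1, 1),
                      composition = c(A = 1, B = 0), k = 1L)
  s_mid <- silhouetteBySubtype(mid, map)
  expect_lt(abs(s_mid["A"]), 0.05)

  # cells sitting on the wrong cluster score strongly negative
  wrong <- methods::new("ProjectionResult",
                        embedding = rbind(c(1, 0.02), c(1, 0.08)),
                        predicted = factor(c("A", "A"), c("A", "B")),
                        confidence = c(1, 1),
                        composition = c(A = 1, B = 0), k = 1L)
  expect_lt(silhouetteBySubtype(wrong, map)["A"], -0.5)

  # a subtype with a single query cell is reported as missing
  single <- methods::new("ProjectionResult",
                         embedding = rbind(c(-1, 0.05)),
                         predicted = factor("A", c("A", "B")),
                         confidence = 1, composition = c(A = 1, B = 0),
                         k = 1L)
  expect_true(is.na(silhouetteBySubtype(single, map)["A"]))
})

test_that("reference-query differential expression is null on random splits", {
  fx <- refFixture()
  st <- "Th1_Effector"
  cells <- which(as.character(subtypeLabels(fx$map)) == st)
  hits <- vapply(1:5, function(i) {
    set.seed(100 + i)
    half <- sample(cells, length(cells) %/% 2)
    pseudo_q <- fx$sce[, half]
    res <- methods::new("ProjectionResult",
                        embedding = refEmbedding(fx$map)[half, , drop = FALSE],
                        predicted = factor(rep(st, length(half)),
                                           levels(subtypeLabels(fx$map))),
                        confidence = rep(1, length(half)),
                        composition = setNames(
                          as.numeric(levels(subtypeLabels(fx$map)) == st),
                          levels(subtypeLabels(fx$map))),
                        k = 1L)
    de <- discriminantGenes(pseudo_q, res, fx$sce[, setdiff(cells, half)],
                            fx$map, st)
    sum(de$padj < 0.05)
  }, 0)
  expect_gte(sum(hits == 0), 4)
})

test_that("planted expression shifts are recovered as discriminant genes", {
  fx <- refFixture()
  q <- queryFixture()
  res <- classifySubtypes(projectCells(q$sce, fx$map), fx$map, k = 20)
  shifted <- c("Gm10001", "Gm10002", "Gm10003", "Gm10004")
  m <- counts(q$sce)
  m[shifted, ] <- m[shifted, ] * 6L
  q2 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = colData(q$sce))
  de <- discriminantGenes(q2, res, fx$sce, fx$map, "Th1_Effector")
  expect_true(all(de[shifted, "padj"] < 0.05))
  expect_true(all(de[shifted, "logFC"] > 0))

  # a gene constant on both sides is uninformative
  zm <- m; zm["Gm10005", ] <- 0L
  rz <- counts(fx$sce); rz["Gm10005", ] <- 0L
  q3 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = zm), colData = colData(q$sce))
  de2 <- discriminantGenes(q3, res, rz, fx$map, "Th1_Effector")
  expect_equal(de2["Gm10005", "p"], 1)
})

test_that("joint re-embedding flags planted novel programs and nothing else", {
  fx <- refFixture()
  # a subsample of the reference is not novel
  sub <- fx$sce[, sample(ncol(fx$sce), 200)]
  re <- recalculateEmbedding(fx$map, fx$sce, sub, seed = 5)
  expect_length(re$novel_clusters, 0)

  # a query dominated by an unrepresented program forms a novel cluster
  mj <- majorSubtypes()
  spec <- cohortSpec(nSamples = 1, cellsPerSample = 250,
                     subtypes = c(mj$subtypes, "Tumoral_Th"),
                     background = c(0.02, 0.02, 0.02, 0.02, 0.01, 0.01, 0.9),
                     nGenes = 300, nMarkerGenes = 20, markerLogFC = 1.5,
                     baselineMean = 5, biasedFraction = 0, seed = 33)
  novel_q <- combineSamples(generateCohort(spec))
  re2 <- recalculateEmbedding(fx$map, fx$sce, novel_q, seed = 5)
  expect_gte(length(re2$novel_clusters), 1)
  novel_cells <- re2$cluster %in% re2$novel_clusters
  expect_true(mean(re2$is_query[novel_cells]) > 0.75)

  # an empty query yields a reference-only map with no flags
  re3 <- recalculateEmbedding(fx$map, fx$sce, NULL, seed = 5)
  expect_length(re3$novel_clusters, 0)
  expect_false(any(re3$is_query))
})

test_that("binomial thinning preserves zeros, totals and composes multiplicatively", {
  fx <- refFixture()
  m <- counts(fx$sce)
  expect_identical(downsampleCounts(m, 1), m)

  thin <- downsampleCounts(m, 0.3, seed = 6)
  total <- sum(m)
  expect_lt(abs(sum(thin) - 0.3 * total),
            4 * sqrt(total * 0.3 * 0.7))
  expect_true(all(thin@x == round(thin@x)))
  expect_true(all(as.matrix(thin) <= as.matrix(m)))

  # thinning by p then q matches thinning by pq in its first moment
  two_step <- downsampleCounts(downsampleCounts(m, 0.6, seed = 7), 0.5,
                               seed = 8)
  expect_lt(abs(sum(two_step) - 0.3 * total),
            4 * sqrt(total * 0.3 * 0.7))

  expect_error(downsampleCounts(m, 0), "in \\(0, 1\\]")
  expect_error(downsampleCounts(m, 1.2), "in \\(0, 1\\]")
})

test_that("depth-robustness curves start at perfect agreement and degrade", {
  fx <- refFixture()
  q <- queryFixture()
  curve <- depthRobustness(q$sce, fx$map, fractions = c(1, 0.05), k = 20,
                           seed = 11)
  expect_equal(curve$agreement[curve$depth_fraction == 1], 1)
  expect_lte(curve$agreement[curve$depth_fraction == 0.05],
             curve$agreement[curve$depth_fraction == 1])
  expect_lt(curve$median_umis[2], curve$median_umis[1])
  # lenient agreement never falls below strict agreement
  rel <- setNames(c("Th1", "Th1", "Tfh", "Tfh", "Tcm", "Tcm"),
                  c("Th1_Effector", "Th1_Memory", "Tfh_Effector",
                    "Tfh_Memory", "Tcmp", "Tcm"))
  curve2 <- depthRobustness(q$sce, fx$map, fractions = 0.1, k = 20,
                            seed = 12, related = rel)
  expect_gte(curve2$lenient_agreement, curve2$agreement)
})
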