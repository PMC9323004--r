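test_that("the bias statistic reaches its documented extremes", {
  q <- c(A = 0.3, B = 0.3, C = 0.4)
  one_hot <- c(A = 1, B = 0, C = 0)
  expect_equal(clonotypeBias(one_hot, q)$c, 1)
  expect_identical(clonotypeBias(one_hot, q)$predominant, "A")
  expect_equal(clonotypeBias(q, q)$c, 0)
})

test_that("the bias statistic matches direct hand evaluation", {
  res <- clonotypeBias(c(s1 = 0.6, s2 = 0.2, s3 = 0.2),
                       c(s1 = 0.4, s2 = 0.3, s3 = 0.3))
  expect_equal(res$c, 1 / 3)
  expect_identical(res$predominant, "s1")
  expect_error(clonotypeBias(c(A = 1, B = 0), c(A = 1, B = 0)), "degenerate")
})

test_that("bias is invariant to subtype relabeling and stays in [0, 1]", {
  set.seed(12)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    f <- as.numeric(rmultinom(1, 15, runif(k))) / 15
    q <- runif(k); q <- q / sum(q)
    names(f) <- names(q) <- paste0("s", seq_len(k))
    c0 <- clonotypeBias(f, q)$c
    expect_gte(c0, 0); expect_lte(c0, 1)
    perm <- sample(k)
    c1 <- clonotypeBias(setNames(f[perm], names(f)),
                        setNames(q[perm], names(q)))$c
    expect_equal(c1, c0)
  }
})

test_that("singleton clones give a degenerate null of mean 1, sd 0", {
  labs <- rep(c("A", "B", "C"), each = 40)
  null <- permutationNull(rep(1L, 120), labs, nPerm = 100, seed = 2)
  expect_equal(null$mean, 1)
  expect_equal(null$sd, 0)
})

test_that("the permutation null matches exhaustive enumeration for small clones", {
  set.seed(3)
  # large singleton pool keeps without-replacement draws close to multinomial
  sizes <- c(rep(1L, 2000), rep(2L, 40))
  labs <- sample(c("A", "B"), sum(sizes), replace = TRUE)
  null <- permutationNull(sizes, labs, nPerm = 2000, seed = 4, minSize = 2)
  q <- subtypeDistribution(labs)
  oracle <- enumBiasNull(2, q)
  bin2 <- null[null$lo == 2, ]
  se_mean <- oracle$sd / sqrt(bin2$n_obs)
  expect_lt(abs(bin2$mean - oracle$mean), 3 * se_mean + 2e-3)
  expect_lt(abs(bin2$sd - oracle$sd),
            3 * oracle$sd / sqrt(2 * (bin2$n_obs - 1)) + 2e-3)
})

test_that("null tables are seed-deterministic and converge with permutations", {
  sizes <- c(rep(1L, 400), rep(12L, 25))
  set.seed(5)
  labs <- sample(paste0("s", 1:6), sum(sizes), replace = TRUE)
  n1 <- permutationNull(sizes, labs, nPerm = 400, seed = 9, minSize = 10)
  n1b <- permutationNull(sizes, labs, nPerm = 400, seed = 9, minSize = 10)
  expect_identical(n1, n1b)
  # doubling the permutations moves bin means by less than 3 MC s.e.
  n2 <- permutationNull(sizes, labs, nPerm = 800, seed = 10, minSize = 10)
  se <- sqrt(n1$sd^2 / n1$n_obs + n2$sd^2 / n2$n_obs)
  expect_true(all(abs(n1$mean - n2$mean) < 3 * se))
})

test_that("common sizes get exact bins while rare sizes pool geometrically", {
  # 40 singleton clones (exact bin) plus scattered rare sizes (pooled)
  sizes <- c(rep(1L, 40), 11L, 13L, 23L, 150L)
  set.seed(6)
  labs <- sample(c("A", "B", "C"), sum(sizes), replace = TRUE)
  null <- permutationNull(sizes, labs, nPerm = 100, seed = 7)
  expect_true(any(null$lo == 1 & null$hi == 1))         # exact-size bin
  expect_true(any(null$lo == 10 & null$hi == 14))       # pooled 11 and 13
  expect_true(any(null$lo == 101 & is.infinite(null$hi)))
  expect_true(all(null$n_obs >= 30))
  # every observed size is covered by exactly one bin
  for (s in unique(sizes)) {
    expect_equal(sum(null$lo <= s & null$hi >= s), 1)
  }
})

test_that("Z-scores flag planted biased clones and spare unbiased cohorts", {
  mj <- list(subtypes = paste0("s", 1:6), background = rep(1 / 6, 6))
  spec <- cohortSpec(nSamples = 1, cellsPerSample = 2500,
                     subtypes = mj$subtypes, background = mj$background,
                     cloneSizeLaw = list(type = "mixture",
                                         large_fraction = 0.5,
                                         large_min = 25, large_max = 60,
                                         small_mean = 2, small_max = 20),
                     biasedFraction = 0.2, plantedBias = 1, seed = 51)
  co <- generateCohort(spec, expression = FALSE)
  tr <- co$truth
  bz <- biasZScores(tr$clonotype_of_cell, tr$subtype_of_cell,
                    tr$sample_of_cell, minSize = 10, nPerm = 500, seed = 52)
  planted <- tr$planted_biased_clones
  big <- planted[planted$size >= 20, ]
  hit <- bz[match(big$key_nt, bz$clone), ]
  expect_true(all(hit$significant))
  expect_identical(as.character(hit$predominant), big$focal_subtype)
  # flags respect the strict threshold convention
  expect_identical(bz$significant, bz$z > 5)

  unb <- generateCohort(cohortSpec(nSamples = 1, cellsPerSample = 2500,
                                   subtypes = mj$subtypes,
                                   background = mj$background,
                                   cloneSizeLaw = list(type = "uniform",
                                                       min = 10, max = 25),
                                   biasedFraction = 0, seed = 53),
                        expression = FALSE)
  bz0 <- biasZScores(unb$truth$clonotype_of_cell, unb$truth$subtype_of_cell,
                     unb$truth$sample_of_cell, minSize = 10, nPerm = 500,
                     seed = 54)
  expect_equal(sum(bz0$significant), 0)
  expect_gte(nrow(bz0), 100)
})

test_that("degenerate null bins yield the documented infinite/zero Z", {
  # clones all of size 1: null sd is 0 and observed bias equals the mean
  labs <- rep(c("A", "B"), each = 30)
  clones <- paste0("cl", seq_along(labs))
  bz <- biasZScores(clones, labs, minSize = 1, nPerm = 100, seed = 3)
  expect_true(all(bz$sd_zero))
  expect_true(all(bz$z == 0))
  expect_false(any(bz$significant))
})

test_that("the normal tail at Z = 5 reproduces the quoted p-value scale", {
  expect_equal(signif(biasTailProbability(5, 2), 2), 5.7e-7)
  expect_equal(biasTailProbability(5, 1), pnorm(-5))
})
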