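test_that("permutation plans are reproducible, label-preserving and synchronized", {
  design <- StudyDesign(sprintf("s%d", 1:8), rep(c("a", "b"), each = 4))
  p1 <- buildPermutationPlan(design, B = 25, seed = 9, exhaustive = "never")
  p2 <- buildPermutationPlan(design, B = 25, seed = 9, exhaustive = "never")
  expect_identical(p1@labelIdx, p2@labelIdx)
  expect_identical(p1@labelIdx[1, ], 1:8)
  oc <- outcome(design)
  for (b in c(1, 13, 25)) {
    expect_identical(sort(as.character(permutedLabels(p1, oc, b))),
                     sort(as.character(oc)))
  }
  # shared samples get identical labels in any two datasets' views
  labA <- permutedLabels(p1, oc, 7, samples = sprintf("s%d", 1:6))
  labB <- permutedLabels(p1, oc, 7, samples = sprintf("s%d", 3:8))
  shared <- sprintf("s%d", 3:6)
  expect_identical(labA[shared], labB[shared])
})

test_that("exhaustive enumeration covers all distinct label arrangements", {
  design <- StudyDesign(sprintf("s%d", 1:6), rep(c("a", "b"), each = 3))
  plan <- buildPermutationPlan(design, B = 19, seed = 1)
  expect_true(plan@exhaustive)
  expect_identical(plan@B, 19L)
  oc <- outcome(design)
  keys <- apply(plan@labelIdx, 1, function(r)
    paste(as.character(oc[r]), collapse = ""))
  expect_identical(length(unique(keys)), 20L)
  # requesting more than the group size without exhaustion warns
  expect_warning(buildPermutationPlan(design, B = 50, seed = 1,
                                      exhaustive = "never"),
                 "distinct non-identity arrangements")
})

test_that("pooled p-values reproduce the augmented estimator and its bounds", {
  # observed 5 vs permutation statistics 1..4: (1 + 0) / 5
  m <- matrix(c(5, 1, 2, 3, 4), 5, 1)
  expect_equal(poolPValues(m)[1, 1], 0.2)
  expect_equal(poolPValues(m)[, 1], c(0.2, 1.0, 0.8, 0.6, 0.4))
  # unique maximum: floor at 1/(B+1) corrected, exactly 0 uncorrected
  expect_equal(poolPValues(m)[1, 1], 1 / 5 * 1)
  big <- matrix(c(9, 1, 2, 3, 4), 5, 1)
  expect_equal(poolPValues(big)[1, 1], 1 / 5)
  expect_equal(poolPValues(big, zeroCorrection = FALSE)[1, 1], 0)
  # total ties: every p-value is 1
  expect_true(all(poolPValues(matrix(2, 6, 2)) == 1))
  # uncorrected pseudo rows are self-inclusive over permutations only
  expect_equal(poolPValues(m, zeroCorrection = FALSE)[, 1],
               c(0, 4, 3, 2, 1) / 4)
})

test_that("combining functions evaluate their closed forms", {
  mk <- function(a, b) list(matrix(a, 1, 1), matrix(b, 1, 1))
  expect_equal(combinePValues(mk(1, 1), "fisher")[1, 1], 0)
  expect_equal(combinePValues(mk(0.5, 0.5), "liptak")[1, 1], 0)
  expect_equal(combinePValues(mk(0.2, 0.7), "tippett")[1, 1], 0.8)
  expect_equal(combinePValues(mk(0.2, 0.7), "fisher")[1, 1],
               -2 * (log(0.2) + log(0.7)))
  # weight annihilation: weight 0 is disallowed, but a tiny weight shows the
  # normalized contribution; exact annihilation via the (1, 0) limit is
  # checked through near-equality
  c1 <- combinePValues(mk(0.2, 0.7),
                       combinerSpec("fisher", c(1, 1e-12)))[1, 1]
  expect_equal(c1, -2 * log(0.2), tolerance = 1e-9)
  expect_error(combinePValues(mk(0, 0.5), "fisher"), "zero-avoidance")
  expect_error(combinerSpec("fisher", c(1, -1)), "positive")
})

test_that("combined statistics are monotone in the evidence", {
  set.seed(61)
  for (cmb in c("fisher", "liptak", "tippett")) {
    lam <- runif(2, 0.2, 0.9)
    base <- combinePValues(list(matrix(lam[1]), matrix(lam[2])), cmb)[1, 1]
    lower <- combinePValues(list(matrix(lam[1] / 2), matrix(lam[2])), cmb)[1, 1]
    expect_gte(lower, base)
  }
})

test_that("exhaustive NPC matches an independent brute-force implementation", {
  toy <- makeToyStudy(nGenes = 30, perGroup = 3, nModalities = 2, seed = 17)
  specs <- list(mod1 = statisticSpec(moderation = FALSE),
                mod2 = statisticSpec(moderation = FALSE))
  res <- runNPC(toy$datasets, toy$design, specs = specs, B = 19, seed = 5)
  expect_identical(res@B, 19L)
  oracle <- bruteForceNPC(toy$mats, rep(c("a", "b"), each = 3))
  tb <- resultTable(res)
  expect_equal(tb$pvalue_partial_mod1, oracle$partial[[1]], tolerance = 1e-12)
  expect_equal(tb$pvalue_partial_mod2, oracle$partial[[2]], tolerance = 1e-12)
  expect_equal(tb$pvalue_global_fisher, oracle$fisher, tolerance = 1e-12)
  expect_equal(tb$pvalue_global_liptak, oracle$liptak, tolerance = 1e-12)
  expect_equal(tb$pvalue_global_tippett, oracle$tippett, tolerance = 1e-12)
})

test_that("a single modality's fisher global p equals its partial p", {
  toy <- makeToyStudy(nGenes = 20, perGroup = 3, nModalities = 1, seed = 23)
  res <- runNPC(toy$datasets, toy$design,
                specs = list(mod1 = statisticSpec(moderation = FALSE)),
                B = 19, seed = 2, combiners = "fisher")
  tb <- resultTable(res)
  expect_equal(tb$pvalue_global_fisher, tb$pvalue_partial_mod1,
               tolerance = 1e-12)
})

test_that("duplicated evidence adds no ranking information under synchronization", {
  toy <- makeToyStudy(nGenes = 40, perGroup = 5, nModalities = 1, seed = 29)
  twin <- list(toy$datasets[[1]],
               OmicsDataset(assayValues(toy$datasets[[1]]), "continuous",
                            "mod2"))
  res <- runNPC(twin, toy$design, B = 99, seed = 3, combiners = "fisher")
  tb <- resultTable(res)
  expect_equal(stats::cor(rank(tb$pvalue_global_fisher),
                          rank(tb$pvalue_partial_mod1)), 1, tolerance = 1e-12)
})

test_that("identical runs are bit-identical and zero-corrected p-values are floored", {
  toy <- makeToyStudy(nGenes = 25, perGroup = 4, nModalities = 2, seed = 37)
  r1 <- runNPC(toy$datasets, toy$design, B = 49, seed = 11)
  r2 <- runNPC(toy$datasets, toy$design, B = 49, seed = 11)
  expect_identical(resultTable(r1), resultTable(r2))
  pv <- unlist(resultTable(r1)[grep("^pvalue", names(resultTable(r1)))])
  expect_gte(min(pv), 1 / (r1@B + 1))
  # FDR adjustment never decreases a p-value
  tb <- resultTable(r1)
  expect_true(all(tb$fdr_global_fisher >= tb$pvalue_global_fisher - 1e-12))
})

test_that("statistic rows depend only on their own plan row", {
  toy <- makeToyStudy(nGenes = 10, perGroup = 3, nModalities = 1, seed = 43)
  design <- toy$design
  plan <- buildPermutationPlan(design, B = 19, seed = 1)
  sw <- plan
  sw@labelIdx[c(3, 8), ] <- sw@labelIdx[c(8, 3), ]
  s1 <- computeStatistics(toy$datasets[[1]], plan, design,
                          statisticSpec(moderation = FALSE))
  s2 <- computeStatistics(toy$datasets[[1]], sw, design,
                          statisticSpec(moderation = FALSE))
  expect_equal(s1[c(3, 8), ], s2[c(8, 3), ], tolerance = 1e-12)
  expect_equal(s1[-c(3, 8), ], s2[-c(3, 8), ], tolerance = 1e-12)

  # B = 0 edge: an identity-only plan returns the observed statistics
  ident <- new("PermutationPlan", B = 0L, seed = 1L,
               labelIdx = matrix(1:6, 1, 6),
               sampleIds = sampleIds(design), exhaustive = FALSE)
  s0 <- computeStatistics(toy$datasets[[1]], ident, design,
                          statisticSpec(moderation = FALSE))
  obs <- linearModelStats(toy$datasets[[1]], design,
                          statisticSpec(moderation = FALSE))
  expect_equal(unname(s0[1, ]), unname(obs$statistic), tolerance = 1e-12)
})

test_that("partially overlapping datasets use consistent shared labels", {
  set.seed(47)
  sidAll <- sprintf("s%02d", 1:12)
  design <- StudyDesign(sidAll, rep(c("a", "b"), 6))
  mA <- matrix(rnorm(8 * 8), 8, 8, dimnames = list(sprintf("g%d", 1:8),
                                                   sidAll[1:8]))
  mB <- matrix(rnorm(8 * 8), 8, 8, dimnames = list(sprintf("g%d", 1:8),
                                                   sidAll[5:12]))
  res <- runNPC(list(OmicsDataset(mA, "continuous", "A"),
                     OmicsDataset(mB, "continuous", "B")),
                design, B = 29, seed = 13,
                specs = list(A = statisticSpec(moderation = FALSE),
                             B = statisticSpec(moderation = FALSE)))
  expect_identical(nrow(resultTable(res)), 8L)
  expect_true(all(resultTable(res)$pvalue_global_fisher > 0))
})

test_that("global null p-values are calibrated", {
  set.seed(53)
  nGenes <- 400
  sid <- sprintf("s%02d", 1:20)
  design <- StudyDesign(sid, rep(c("a", "b"), each = 10))
  mats <- lapply(1:2, function(i)
    matrix(rnorm(nGenes * 20), nGenes, 20,
           dimnames = list(sprintf("g%03d", 1:nGenes), sid)))
  datasets <- list(OmicsDataset(mats[[1]], "continuous", "m1"),
                   OmicsDataset(mats[[2]], "continuous", "m2"))
  res <- runNPC(datasets, design, B = 200, seed = 19, combiners = "fisher")
  pg <- resultTable(res)$pvalue_global_fisher
  for (alpha in c(0.05, 0.1)) {
    hits <- sum(pg <= alpha)
    bounds <- qbinom(c(0.005, 0.995), nGenes, alpha)
    expect_gte(hits, bounds[1])
    expect_lte(hits, bounds[2])
  }
})

test_that("freedman-lane permutation adjusts for covariates", {
  set.seed(59)
  n <- 16
  sid <- sprintf("s%02d", seq_len(n))
  age <- rnorm(n)
  design <- StudyDesign(sid, rep(c("a", "b"), each = n / 2),
                        covariates = data.frame(age = age,
                                                row.names = sid))
  # outcome-independent genes driven by the covariate only
  Y <- matrix(rep(2 * age, each = 20), 20, n,
              dimnames = list(sprintf("g%02d", 1:20), sid)) +
       matrix(rnorm(20 * n, sd = 0.5), 20, n)
  ds <- OmicsDataset(Y, "continuous", "m1")
  plan <- buildPermutationPlan(design, B = 99, seed = 7, exhaustive = "never")
  sfl <- computeStatistics(ds, plan, design, statisticSpec(moderation = FALSE),
                           permScheme = "freedman-lane")
  lam <- poolPValues(sfl)[1, ]
  expect_gt(suppressWarnings(stats::ks.test(lam, "punif")$p.value), 0.01)
})
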