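test_that("parametric Fisher combination evaluates the chi-square closed form", {
  expect_equal(cpFisher(cbind(1, 1)), 1)
  expect_equal(cpFisher(cbind(0.5, 0.5)),
               stats::pchisq(-2 * (log(0.5) + log(0.5)), df = 4,
                             lower.tail = FALSE))
  expect_equal(round(cpFisher(cbind(0.5, 0.5)), 4), 0.5966)
  # k = 1: the combination returns the input p-value
  p <- c(0.01, 0.2, 0.77)
  expect_equal(cpFisher(matrix(p, ncol = 1)), p, tolerance = 1e-12)
  expect_error(cpFisher(cbind(0, 0.5)), "strictly positive")
})

test_that("cpFisher is calibrated under independence, anti-conservative under duplication", {
  set.seed(71)
  u <- matrix(runif(2 * 10000), ncol = 2)
  pc <- cpFisher(u)
  expect_gt(suppressWarnings(stats::ks.test(pc, "punif")$p.value), 0.01)
  # perfectly correlated partial p-values: type-I error exceeds the level
  dup <- runif(10000)
  pd <- cpFisher(cbind(dup, dup))
  expect_gt(mean(pd <= 0.05), 0.05)
})

test_that("ranking uses midranks and is monotone-invariant", {
  expect_equal(rankFeatures(c(0.01, 0.5, 0.9)), c(1, 2, 3))
  expect_equal(rankFeatures(c(0.2, 0.2, 0.9)), c(1.5, 1.5, 3))
  x <- runif(50)
  expect_equal(rankFeatures(x), rankFeatures(pmin(1, x^3)), tolerance = 1e-12)
  # statistics: extremes of sum and product
  rk <- cbind(c(1, 10), c(1, 10))
  expect_equal(rankSumStat(rk), c(2, 20))
  expect_equal(rankProdStat(rk), c(1, 100))
})

test_that("rank-product approximation has the stated boundary behaviour", {
  # full mass and the single-uniform identity
  expect_equal(rankProdApproxPValue(10^2, 2, 10), 1)
  expect_equal(rankProdApproxPValue(7, 1, 10), 0.7)
  expect_error(rankProdApproxPValue(200, 2, 10), "out of range")
  # monotone in rho
  p <- rankProdApproxPValue(1:100, 2, 10)
  expect_true(all(diff(p) >= 0))
  # the continuous gamma tail is exact for the product of two uniforms
  q <- 0.037
  mc <- stats::integrate(function(u) pmin(1, q / u), 0, 1)$value
  expect_equal(rankProdApproxPValue(q * 100, 2, 10), mc, tolerance = 1e-4)
})

test_that("partial-conjunction p-value follows the ordered-minimum formula", {
  expect_equal(benjaminiPartialConjunction(c(0.01, 0.04, 0.9), u = 1), 0.03)
  # u = n: the largest partial p-value
  expect_equal(benjaminiPartialConjunction(c(0.2, 0.05, 0.6), u = 3), 0.6)
  expect_error(benjaminiPartialConjunction(c(0.1, 0.2), u = 3), "exceed")
  # u = 1 equals the minimum BH-adjusted p-value, exactly, on random vectors
  set.seed(73)
  for (i in 1:200) {
    p <- runif(sample(2:6, 1))
    expect_equal(benjaminiPartialConjunction(p, u = 1),
                 min(stats::p.adjust(p, "BH")), tolerance = 1e-12)
  }
})

test_that("NPC-wrapped rank combination matches a brute-force enumeration", {
  toy <- makeToyStudy(nGenes = 15, perGroup = 3, nModalities = 2, seed = 79)
  specs <- list(mod1 = statisticSpec(moderation = FALSE),
                mod2 = statisticSpec(moderation = FALSE))
  p <- npcRankCombine(toy$datasets, toy$design, statistic = "sum",
                      B = 19, seed = 3, specs = specs)
  # brute force: |t| per assignment, within-row ranks (1 = largest |t|),
  # pooled self-inclusively on the negated rank sum
  assigns <- enumerateTwoGroupLabels(rep(c("a", "b"), each = 3))
  G <- 15
  rkSum <- matrix(0, length(assigns), G)
  for (m in toy$mats) {
    S <- matrix(NA_real_, length(assigns), G)
    for (b in seq_along(assigns)) {
      for (g in seq_len(G)) {
        S[b, g] <- abs(stats::t.test(m[g, assigns[[b]] == "b"],
                                     m[g, assigns[[b]] == "a"],
                                     var.equal = TRUE)$statistic)
      }
      rkSum[b, ] <- rkSum[b, ] + rank(-S[b, ])
    }
  }
  oracle <- vapply(seq_len(G), function(g)
    sum(rkSum[, g] <= rkSum[1, g]) / nrow(rkSum), numeric(1))
  expect_equal(unname(p), oracle, tolerance = 1e-12)
})

test_that("single-modality rank combination is a monotone transform of the statistic", {
  toy <- makeToyStudy(nGenes = 25, perGroup = 4, nModalities = 1, seed = 83)
  p <- npcRankCombine(toy$datasets, toy$design, statistic = "product",
                      B = 49, seed = 5,
                      specs = list(mod1 = statisticSpec(moderation = FALSE)))
  obs <- linearModelStats(toy$datasets[[1]], toy$design,
                          statisticSpec(moderation = FALSE))$statistic
  # monotone up to pooled-tie granularity (p-values live on a 1/(B+1) grid)
  expect_gte(stats::cor(rank(p), rank(-obs)), 0.95)
})

test_that("baseline and synchronized rank p-values agree under independence but not under duplication", {
  set.seed(89)
  sid <- sprintf("s%02d", 1:20)
  design <- StudyDesign(sid, rep(c("a", "b"), each = 10))
  gid <- sprintf("g%03d", 1:150)
  m1 <- matrix(rnorm(150 * 20), 150, 20, dimnames = list(gid, sid))
  m2 <- matrix(rnorm(150 * 20), 150, 20, dimnames = list(gid, sid))
  indep <- list(OmicsDataset(m1, "continuous", "m1"),
                OmicsDataset(m2, "continuous", "m2"))
  pBase <- baselineRankPValues(indep, design, "sum", B = 99, seed = 7)
  pSync <- npcRankCombine(indep, design, "sum", B = 99, seed = 7)
  expect_gt(suppressWarnings(stats::ks.test(pBase, pSync)$p.value), 0.01)

  # duplicated null datasets: the independent-permutation baseline loses
  # uniformity while the synchronized version keeps it
  dup <- list(OmicsDataset(m1, "continuous", "m1"),
              OmicsDataset(m1, "continuous", "m2"))
  pBaseDup <- baselineRankPValues(dup, design, "sum", B = 99, seed = 7)
  pSyncDup <- npcRankCombine(dup, design, "sum", B = 99, seed = 7)
  expect_lt(suppressWarnings(stats::ks.test(pBaseDup, "punif")$p.value), 0.01)
  expect_gt(suppressWarnings(stats::ks.test(pSyncDup, "punif")$p.value), 0.01)

  # determinism under a fixed seed
  expect_identical(pBase,
                   baselineRankPValues(indep, design, "sum", B = 99, seed = 7))
})

test_that("the method registry shares inputs consistently across methods", {
  toy <- makeToyStudy(nGenes = 30, perGroup = 5, nModalities = 2, seed = 97)
  pv <- runIntegration(toy$datasets, toy$design,
                       methods = c("npc-fisher", "npc-nocorr-fisher", "cp",
                                   "benjamini", "rankprod", "single-mod1"),
                       B = 99, seed = 11)
  expect_identical(colnames(pv),
                   c("npc-fisher", "npc-nocorr-fisher", "cp", "benjamini",
                     "rankprod", "single-mod1"))
  expect_true(all(pv[, "npc-fisher"] >= 1 / 100))
  expect_true(all(pv >= 0 & pv <= 1))
  # benjamini at u = 1 can never beat the smallest scaled partial p
  pm <- cbind(parametricPValues(toy$datasets[[1]], toy$design),
              parametricPValues(toy$datasets[[2]], toy$design))
  expect_equal(unname(pv[, "benjamini"]),
               unname(apply(pm, 1, function(p) min(p.adjust(p, "BH")))),
               tolerance = 1e-12)
  expect_error(runIntegration(toy$datasets, toy$design, methods = "nope"),
               "unknown method")
})
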