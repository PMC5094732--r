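test_that("design matrices include intercept, covariates, and catch rank deficiency", {
  sid <- sprintf("s%d", 1:6)
  d0 <- StudyDesign(sid, rep(c("a", "b"), each = 3))
  dm <- designMatrix(d0, outcome(d0))
  expect_identical(dim(dm$X), c(6L, 2L))
  expect_identical(dm$outcomeCols, 2L)

  d1 <- StudyDesign(sid, rep(c("a", "b"), each = 3),
                    covariates = data.frame(age = c(31, 45, 52, 38, 60, 41)))
  dm1 <- designMatrix(d1, outcome(d1))
  expect_identical(dim(dm1$X), c(6L, 3L))

  d2 <- StudyDesign(sid, rep(c("a", "b"), each = 3),
                    covariates = data.frame(const = rep(1, 6)))
  expect_error(designMatrix(d2, outcome(d2)), "rank-deficient")
})

test_that("OLS t equals the pooled two-sample t without covariates", {
  set.seed(101)
  Y <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  design <- StudyDesign(colnames(Y), rep(c("a", "b"), each = 5))
  st <- linearModelStats(Y, design, statisticSpec("linear_model_t",
                                                  moderation = FALSE))
  oracle <- vapply(1:20, function(g)
    stats::t.test(Y[g, 6:10], Y[g, 1:5], var.equal = TRUE)$statistic,
    numeric(1))
  expect_equal(unname(st$raw), unname(oracle), tolerance = 1e-10)
  expect_identical(st$df, 8L)
  # t statistics are equivariant under positive feature scaling
  st2 <- linearModelStats(Y * 7, design, statisticSpec("linear_model_t",
                                                       moderation = FALSE))
  expect_equal(st$raw, st2$raw, tolerance = 1e-12)
})

test_that("moderated t interpolates between ordinary t and the prior limit", {
  set.seed(7)
  Y <- matrix(rnorm(300, sd = rep(c(0.5, 2), each = 15)), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  design <- StudyDesign(colnames(Y), rep(c("a", "b"), each = 5))
  plain <- linearModelStats(Y, design, statisticSpec(moderation = FALSE))
  # d0 = 0: no shrinkage, moderated t equals ordinary t
  m0 <- linearModelStats(Y, design, statisticSpec(moderation = TRUE),
                         moderationParams = list(d0 = 0, s02 = 1))
  expect_equal(m0$raw, plain$raw, tolerance = 1e-12)
  # d0 = Inf: full shrinkage, every variance replaced by s02
  mInf <- linearModelStats(Y, design, statisticSpec(moderation = TRUE),
                           moderationParams = list(d0 = Inf, s02 = 1.3))
  beta <- plain$raw * sqrt((apply(Y[, 6:10], 1, var) * 4 +
                            apply(Y[, 1:5], 1, var) * 4) / 8 * (2 / 5))
  expect_equal(unname(mInf$raw), unname(beta / sqrt(1.3 * 2 / 5)),
               tolerance = 1e-10)
  # data-driven moderation matches limma's empirical-Bayes t exactly
  fit <- limma::eBayes(limma::lmFit(Y, cbind(1, rep(0:1, each = 5))))
  mEB <- linearModelStats(Y, design, statisticSpec(moderation = TRUE))
  expect_equal(unname(mEB$raw), unname(fit$t[, 2]), tolerance = 1e-10)
})

test_that("perfect separation yields a flagged sentinel statistic", {
  Y <- matrix(rep(c(0, 0, 0, 1, 1, 1), 2), 2, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  design <- StudyDesign(colnames(Y), rep(c("a", "b"), each = 3))
  st <- linearModelStats(Y, design, statisticSpec(moderation = FALSE))
  expect_true(all(st$flagged))
  expect_true(all(abs(st$raw) >= 1e100))
})

test_that("voom transform matches the offset formula and yields positive weights", {
  set.seed(11)
  cnt <- matrix(rnbinom(400, mu = 150, size = 4), 40, 10,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:10)))
  ds <- OmicsDataset(cnt, "counts", "rna")
  X <- cbind(1, rep(0:1, each = 5))
  vt <- voomTransform(ds, X)
  manual <- log2(t((t(cnt) + 0.5) / (colSums(cnt) + 1)) * 1e6)
  expect_equal(vt$logcpm, manual, tolerance = 1e-12)
  expect_true(all(is.finite(vt$weights)) && all(vt$weights > 0))

  # constant counts: symmetric in genes and samples
  const <- matrix(50L, 6, 4, dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  vc <- voomTransform(OmicsDataset(const, "counts", "rna"),
                      cbind(1, rep(0:1, each = 2)))
  expect_lt(diff(range(vc$logcpm)), 1e-12)
  expect_lt(diff(range(vc$weights)), 1e-6)

  # doubling all counts of one sample barely moves its logcpm (offset bound)
  c2 <- const; c2[, 1] <- c2[, 1] * 2L
  v2 <- voomTransform(OmicsDataset(c2, "counts", "rna"),
                      cbind(1, rep(0:1, each = 2)))
  bound <- log2((50 + 0.5) / (50 + 0.25))
  expect_lt(max(abs(v2$logcpm[, 1] - vc$logcpm[, 1])), bound)

  zero <- const; zero[, 2] <- 0L
  expect_error(voomTransform(OmicsDataset(zero, "counts", "rna"), X[1:4, ]),
               "zero total counts")
})

test_that("genotype trend statistic matches the closed-form Cochran-Armitage value", {
  # maximal trend: cases all dosage 2, controls all dosage 0
  g <- matrix(c(rep(0, 10), rep(2, 10)), 1, 20,
              dimnames = list("snp1", sprintf("s%02d", 1:20)))
  grp <- rep(c("control", "case"), each = 10)  # levels: case < control
  st <- genotypeTrendStat(OmicsDataset(g, "genotype", "snp"), grp)
  expect_equal(unname(st$z^2), caTrendChisq(cases = c(0, 0, 10),
                                            controls = c(10, 0, 0)),
               tolerance = 1e-12)
  expect_equal(unname(st$z^2), 20, tolerance = 1e-12)

  # agrees with prop.trend.test on random tables
  set.seed(21)
  gm <- matrix(sample(0:2, 15 * 20, replace = TRUE), 15, 20,
               dimnames = list(sprintf("snp%02d", 1:15), sprintf("s%02d", 1:20)))
  st2 <- genotypeTrendStat(OmicsDataset(gm, "genotype", "snp"), grp)
  oracle <- vapply(1:15, function(j) {
    tab <- table(factor(grp), factor(gm[j, ], levels = 0:2))
    keep <- colSums(tab) > 0
    unname(suppressWarnings(stats::prop.trend.test(
      tab["case", keep], colSums(tab)[keep],
      score = as.numeric(colnames(tab)[keep]))$statistic))
  }, numeric(1))
  expect_equal(unname(st2$z^2), oracle, tolerance = 1e-10)

  # antisymmetric under label swap; zero for identical group distributions
  stSwap <- genotypeTrendStat(OmicsDataset(gm, "genotype", "snp"),
                              rev(grp))
  expect_equal(st2$z, -stSwap$z, tolerance = 1e-12)
  sym <- matrix(rep(c(0, 1, 2, 0, 1, 2), 2), 2, 6, byrow = TRUE,
                dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  stSym <- genotypeTrendStat(OmicsDataset(sym, "genotype", "snp"),
                             rep(c("x", "y"), 3))
  expect_equal(unname(stSym$z), c(0, 0))
  mono <- matrix(1, 1, 6, dimnames = list("m", sprintf("s%d", 1:6)))
  stM <- genotypeTrendStat(OmicsDataset(mono, "genotype", "snp"),
                           rep(c("x", "y"), 3))
  expect_true(stM$flagged && stM$z == 0)
})

test_that("rank-sum statistic handles extremes, ties, and matches enumeration", {
  sid <- sprintf("s%d", 1:6)
  grp <- rep(c("a", "b"), each = 3)
  # perfectly separated: first group holds ranks 1..3
  m <- matrix(1:6, 1, 6, dimnames = list("f", sid))
  st <- ranksumStat(OmicsDataset(m, "uniform_like", "u"), grp)
  expect_equal(unname(st$W), 6)
  # fully tied: W equals its null expectation, z = 0
  tied <- matrix(5, 1, 6, dimnames = list("f", sid))
  stT <- ranksumStat(OmicsDataset(tied, "uniform_like", "u"), grp)
  expect_equal(unname(stT$W), 3 * (6 + 1) / 2)
  expect_equal(unname(stT$z), 0)

  # exact one-sided p from the 20 label assignments vs the (continuity-
  # corrected) normal approximation, for every attainable rank sum
  wAll <- apply(utils::combn(6, 3), 2, sum)
  E <- 3 * 7 / 2
  sdW <- sqrt(3 * 3 * 7 / 12)
  for (w in unique(wAll)) {
    exactP <- mean(wAll >= w)
    approxP <- stats::pnorm((w - E - 0.5) / sdW, lower.tail = FALSE)
    expect_lt(abs(approxP - exactP), 0.05)
  }

  expect_error(ranksumStat(OmicsDataset(tied, "uniform_like", "u"),
                           rep("a", 6)), "dichotomous")
})

test_that("multiclass outcomes use the partial F statistic", {
  set.seed(41)
  Y <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:12)))
  design <- StudyDesign(colnames(Y), rep(c("a", "b", "c"), each = 4))
  st <- linearModelStats(Y, design, statisticSpec("linear_model_F",
                                                  moderation = FALSE))
  oracle <- vapply(1:10, function(g) {
    fit <- stats::lm(Y[g, ] ~ factor(rep(c("a", "b", "c"), each = 4)))
    unname(summary(fit)$fstatistic[1])
  }, numeric(1))
  expect_equal(unname(st$raw), oracle, tolerance = 1e-10)
  expect_identical(st$df, c(2L, 9L))
})

test_that("parametric p-values are valid and scale-free where expected", {
  set.seed(51)
  toy <- makeToyStudy(nGenes = 25, perGroup = 5, nModalities = 1, seed = 3)
  ds <- toy$datasets[[1]]
  p1 <- parametricPValues(ds, toy$design)
  expect_true(all(p1 > 0 & p1 <= 1))
  # rank-sum p-values are invariant under monotone transforms of the data
  u <- OmicsDataset(exp(assayValues(ds)), "uniform_like", "u")
  u2 <- OmicsDataset(assayValues(ds), "uniform_like", "u")
  expect_equal(parametricPValues(u, toy$design),
               parametricPValues(u2, toy$design), tolerance = 1e-12)
})
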