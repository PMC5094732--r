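#' Parametric Fisher combination of per-modality p-values (CP)
#'
#' The classical parametric meta-analysis: per-feature partial p-values
#' from each modality's own parametric test are combined as
#' `X = -2 * sum_i log(p_i)` and referred to a chi-square distribution with
#' `2k` degrees of freedom (upper tail). Valid under independence of the
#' partial tests; anti-conservative when modalities are positively
#' correlated, which is exactly the failure mode the permutation-based NPC
#' avoids.
#'
#' @param partialP numeric matrix, features x modalities, of parametric
#'   p-values in (0, 1] (a vector is treated as a single feature).
#' @return numeric vector of global p-values.
#' @examples
#' cpFisher(cbind(0.5, 0.5))  # ~ 0.5966
#' @export
cpFisher <- function(partialP) {
  if (is.null(dim(partialP))) partialP <- matrix(partialP, nrow = 1L)
  if (any(partialP <= 0)) {
    stop("parametric partial p-values must be strictly positive")
  }
  if (any(partialP > 1)) stop("p-values above 1")
  k <- ncol(partialP)
  X <- -2 * rowSums(log(partialP))
  stats::pchisq(X, df = 2 * k, lower.tail = FALSE)
}

#' Rank features by per-modality evidence
#'
#' Ascending ranks on the evidence (by default p-values, smaller = stronger
#' so rank 1 is the strongest feature), with midranks for ties. Ranks are
#' invariant under any strictly monotone transform of the evidence.
#'
#' @param evidence numeric vector or features x modalities matrix.
#' @param smallerIsStronger orientation of the evidence (default TRUE, as
#'   for p-values).
#' @return object of the same shape holding ranks.
#' @export
rankFeatures <- function(evidence, smallerIsStronger = TRUE) {
  rk1 <- function(v) rank(if (smallerIsStronger) v else -v)
  if (is.null(dim(evidence))) return(rk1(evidence))
  apply(evidence, 2L, rk1)
}

#' Rank-sum and rank-product global statistics
#'
#' Combine per-modality ranks into a single statistic per feature: the sum
#' (RankSum) or product (RankProd) over modalities. Smaller values mean
#' stronger evidence of global deregulation.
#'
#' @param ranks features x modalities rank matrix from [rankFeatures()].
#' @return numeric vector of per-feature statistics.
#' @export
rankSumStat <- function(ranks) rowSums(as.matrix(ranks))

#' @rdname rankSumStat
#' @export
rankProdStat <- function(ranks) {
  m <- as.matrix(ranks)
  exp(rowSums(log(m)))
}

#' Approximate p-value for a rank product
#'
#' Continuous approximation to the null distribution of the rank product
#' of k independent uniform rankings of n features: treating each scaled
#' rank as Uniform(0,1), `P(prod_i U_i <= q)` with `q = rho / n^k` has the
#' closed gamma-tail form `q * sum_{j=0}^{k-1} (-log q)^j / j!`. This is
#' the correlation-naive baseline significance for the RankProd method.
#'
#' @param rho rank product value(s), in `[1, n^k]`.
#' @param k number of modalities.
#' @param n number of features ranked.
#' @return numeric vector of approximate p-values (clamped to at most 1).
#' @export
rankProdApproxPValue <- function(rho, k, n) {
  if (any(rho < 1 - 1e-9) || any(rho > n^k + 1e-9)) {
    stop(sprintf("rank product out of range [1, %g]", n^k))
  }
  q <- pmin(rho / n^k, 1)
  lq <- -log(q)
  p <- numeric(length(q))
  term <- rep(1, length(q))
  for (j in seq_len(k) - 1L) {
    if (j > 0L) term <- term * lq / j
    p <- p + term
  }
  pmin(q * p, 1)
}

# rank (B+1) x features statistic rows: rank 1 = strongest (largest statistic)
.rankRows <- function(statMatrix) {
  t(apply(statMatrix, 1L, function(r) rank(-r)))
}

# shared core: combined rank statistic per row, pooled p-values per feature
.rankCombineFromStats <- function(statList, statistic, zeroCorrection) {
  combined <- NULL
  for (M in statList) {
    rk <- .rankRows(M)
    combined <- if (is.null(combined)) {
      if (statistic == "sum") rk else log(rk)
    } else {
      if (statistic == "sum") combined + rk else combined + log(rk)
    }
  }
  # smaller combined rank = stronger evidence; pool on the negated statistic
  poolPValues(-combined, zeroCorrection = zeroCorrection)[1L, ]
}

#' NPC-wrapped rank combination (synchronized permutations)
#'
#' Uses the NPC permutation schema to assign p-values to the RankSum /
#' RankProd statistics: for every permutation (the same one across all
#' modalities), per-modality statistics are recomputed, features are ranked
#' within each modality (rank 1 = strongest evidence, midranks for ties),
#' and the sum or product of ranks is formed per feature. The global
#' p-value comes from the self-inclusive pooled comparison of the B + 1
#' combined rank statistics, so between-dataset correlations are carried
#' into the null distribution.
#'
#' @param datasets list of [OmicsDataset-class] objects.
#' @param design a [StudyDesign-class].
#' @param statistic `"sum"` or `"product"`.
#' @param B,seed,specs,zeroCorrection,exhaustive as in [runNPC()].
#' @param plan optional pre-built [PermutationPlan-class] (shared with an
#'   NPC run).
#' @return named numeric vector of per-feature global p-values.
#' @export
npcRankCombine <- function(datasets, design, statistic = c("sum", "product"),
                           B = 1000L, seed = 1L, specs = NULL,
                           zeroCorrection = TRUE, plan = NULL,
                           exhaustive = "auto") {
  statistic <- match.arg(statistic)
  if (is.null(plan)) {
    plan <- buildPermutationPlan(design, B = B, seed = seed,
                                 exhaustive = exhaustive)
  }
  statList <- lapply(datasets, function(d) {
    sp <- if (!is.null(specs) && modalityId(d) %in% names(specs))
            specs[[modalityId(d)]] else defaultStatisticSpec(d, design)
    computeStatistics(d, plan, design, sp)
  })
  .rankCombineFromStats(statList, statistic, zeroCorrection)
}

#' Correlation-naive rank combination baseline
#'
#' Identical pipeline to [npcRankCombine()] except that every modality
#' receives its own, independently drawn permutation plan. Breaking the
#' synchronization deliberately discards between-dataset dependence: on
#' independent datasets the baseline and the NPC-wrapped version agree in
#' distribution, but under cross-dataset correlation the baseline's null
#' distribution is wrong and its p-values become miscalibrated -- the
#' classical meta-analysis failure mode.
#'
#' @inheritParams npcRankCombine
#' @return named numeric vector of per-feature global p-values.
#' @export
baselineRankPValues <- function(datasets, design,
                                statistic = c("sum", "product"),
                                B = 1000L, seed = 1L, specs = NULL,
                                zeroCorrection = TRUE) {
  statistic <- match.arg(statistic)
  statList <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    plan <- buildPermutationPlan(design, B = B,
                                 seed = as.integer(seed) + 7919L * i,
                                 exhaustive = "never")
    sp <- if (!is.null(specs) && modalityId(d) %in% names(specs))
            specs[[modalityId(d)]] else defaultStatisticSpec(d, design)
    statList[[i]] <- computeStatistics(d, plan, design, sp)
  }
  .rankCombineFromStats(statList, statistic, zeroCorrection)
}

#' Benjamini-Heller partial-conjunction p-value
#'
#' Tests whether at least `u` of the `n` partial null hypotheses are false.
#' With the partial p-values sorted ascending (lambda_(1) <= ... <=
#' lambda_(n)), the global p-value is
#' `min_{j = 1..n-u+1} ((n - u + 1) / j) * lambda_(u - 1 + j)`, clamped to
#' at most 1. At `u = 1` this reduces to the minimum Benjamini-Hochberg
#' adjusted p-value; at `u = n` it is the largest partial p-value.
#'
#' @param partialP numeric vector (one feature) or features x modalities
#'   matrix of partial p-values.
#' @param u required number of false partial nulls, `1 <= u <= n`.
#' @return per-feature partial-conjunction p-value.
#' @export
benjaminiPartialConjunction <- function(partialP, u = 1L) {
  one <- function(p) {
    n <- length(p)
    if (u > n) stop("u cannot exceed the number of partial p-values")
    ps <- sort(p)
    j <- seq_len(n - u + 1L)
    min(1, min((n - u + 1L) / j * ps[u - 1L + j]))
  }
  if (is.null(dim(partialP))) return(one(partialP))
  apply(partialP, 1L, one)
}

#' Names of the available integration methods
#'
#' @return character vector of method names accepted by
#'   [runIntegration()]: the NPC combiners (`npc-fisher`, `npc-liptak`,
#'   `npc-tippett`), their uncorrected variants (`npc-nocorr-*`), the
#'   NPC-wrapped rank methods (`npc-ranksum`, `npc-rankprod`), the
#'   correlation-naive baselines (`ranksum`, `rankprod`), the parametric
#'   combination (`cp`) and the partial-conjunction test (`benjamini`).
#'   Single-modality parametric analyses are available as
#'   `single-<modalityId>`.
#' @export
integrationMethods <- function() {
  c("npc-fisher", "npc-liptak", "npc-tippett",
    "npc-nocorr-fisher", "npc-nocorr-liptak", "npc-nocorr-tippett",
    "npc-ranksum", "npc-rankprod", "ranksum", "rankprod", "cp", "benjamini")
}

#' Run several integration methods on the same data
#'
#' Computes per-feature global p-values for each requested method, sharing
#' intermediate results (one synchronized permutation plan and one set of
#' statistic matrices serve all NPC-based methods; one set of parametric
#' per-modality p-values serves `cp`, `benjamini`, `rankprod` and the
#' single-modality analyses).
#'
#' Method constructions: `rankprod` ranks features on the parametric
#' per-modality p-values and applies the gamma-tail approximation to the
#' rank product; `ranksum` uses independently drawn permutation plans per
#' modality (see [baselineRankPValues()]); `benjamini` uses `u = 1`.
#'
#' @param datasets list of [OmicsDataset-class] objects.
#' @param design a [StudyDesign-class].
#' @param methods character vector of method names; see
#'   [integrationMethods()].
#' @param B,seed,specs,exhaustive as in [runNPC()].
#' @return numeric matrix, features x methods, of p-values.
#' @export
runIntegration <- function(datasets, design, methods = integrationMethods(),
                           B = 1000L, seed = 1L, specs = NULL,
                           exhaustive = "auto") {
  mids <- vapply(datasets, modalityId, character(1L))
  names(datasets) <- mids
  known <- c(integrationMethods(), paste0("single-", mids))
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop(sprintf("unknown method(s): %s; available: %s",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  getSpec <- function(d) {
    if (!is.null(specs) && modalityId(d) %in% names(specs))
      specs[[modalityId(d)]] else defaultStatisticSpec(d, design)
  }
  feats <- Reduce(intersect, lapply(datasets, featureIds))
  datasets <- lapply(datasets, function(d)
    OmicsDataset(assayValues(d)[feats, , drop = FALSE], modalityKind(d),
                 modalityId(d)))
  out <- matrix(NA_real_, length(feats), length(methods),
                dimnames = list(feats, methods))

  needsPlan <- any(grepl("^npc-", methods))
  statList <- NULL
  if (needsPlan) {
    plan <- buildPermutationPlan(design, B = B, seed = seed,
                                 exhaustive = exhaustive)
    statList <- lapply(datasets, function(d)
      computeStatistics(d, plan, design, getSpec(d)))
  }
  npcComb <- intersect(methods, c("npc-fisher", "npc-liptak", "npc-tippett"))
  if (length(npcComb)) {
    cube <- lapply(statList, poolPValues, zeroCorrection = TRUE)
    for (m in npcComb) {
      cmb <- sub("^npc-", "", m)
      out[, m] <- globalPValue(combinePValues(cube, cmb), TRUE)
    }
  }
  npcNoc <- intersect(methods, c("npc-nocorr-fisher", "npc-nocorr-liptak",
                                 "npc-nocorr-tippett"))
  if (length(npcNoc)) {
    cube0 <- lapply(statList, poolPValues, zeroCorrection = FALSE)
    for (m in npcNoc) {
      cmb <- sub("^npc-nocorr-", "", m)
      out[, m] <- globalPValue(combinePValues(cube0, cmb, allowZero = TRUE),
                               FALSE)
    }
  }
  for (m in intersect(methods, c("npc-ranksum", "npc-rankprod"))) {
    stat <- if (m == "npc-ranksum") "sum" else "product"
    out[, m] <- .rankCombineFromStats(statList, stat, TRUE)
  }
  if ("ranksum" %in% methods) {
    out[, "ranksum"] <- baselineRankPValues(datasets, design, "sum",
                                            B = B, seed = seed, specs = specs)
  }
  needsParam <- intersect(methods,
                          c("cp", "benjamini", "rankprod",
                            paste0("single-", mids)))
  if (length(needsParam)) {
    pmat <- vapply(datasets, function(d)
      parametricPValues(d, design, getSpec(d)), numeric(length(feats)))
    pmat <- matrix(pmat, nrow = length(feats),
                   dimnames = list(feats, mids))
    if ("cp" %in% methods) out[, "cp"] <- cpFisher(pmat)
    if ("benjamini" %in% methods) {
      out[, "benjamini"] <- benjaminiPartialConjunction(pmat, u = 1L)
    }
    if ("rankprod" %in% methods) {
      rho <- rankProdStat(rankFeatures(pmat))
      out[, "rankprod"] <- rankProdApproxPValue(rho, k = ncol(pmat),
                                                n = length(feats))
    }
    for (m in grep("^single-", methods, value = TRUE)) {
      out[, m] <- pmat[, sub("^single-", "", m)]
    }
  }
  out
}
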