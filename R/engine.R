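#' Build a synchronized permutation plan
#'
#' Materializes B rearrangements of the observed outcome over the sample
#' universe, plus the identity as row 0. All modalities later read their
#' samples' labels from the same plan, so shared samples receive identical
#' relabelings in every permutation -- the mechanism that preserves
#' between-dataset correlations under the global null.
#'
#' Permutations are sampled uniformly with replacement from the permutation
#' group. For a dichotomous outcome whose number of distinct label
#' arrangements (choose(n, n2)) minus one does not exceed B, all distinct
#' non-identity arrangements are enumerated instead (`exhaustive = "auto"`),
#' making the permutation p-values exact.
#'
#' @param design a [StudyDesign-class]; the outcome must be defined on every
#'   universe sample.
#' @param B requested number of permutations (>= 1).
#' @param seed integer RNG seed; the plan is fully determined by
#'   (seed, B, universe order).
#' @param exhaustive `"auto"` (default), `"never"` or `"always"` (dichotomous
#'   outcomes only).
#' @return a [PermutationPlan-class]; its `B` may differ from the request
#'   when exhaustive enumeration is used.
#' @export
buildPermutationPlan <- function(design, B, seed = 1L,
                                 exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  stopifnot(B >= 1L)
  universe <- sampleIds(design)
  n <- length(universe)
  oc <- outcome(design)
  # number of distinct label arrangements of the outcome multiset
  counts <- if (outcomeType(design) == "continuous") rep(1L, n) else table(oc)
  logA <- lfactorial(n) - sum(lfactorial(counts))
  A <- if (logA < log(.Machine$integer.max)) round(exp(logA)) else Inf

  doExhaustive <- FALSE
  if (outcomeType(design) == "dichotomous" &&
      (exhaustive == "always" || (exhaustive == "auto" && A - 1 <= B))) {
    doExhaustive <- TRUE
  } else if (exhaustive == "always") {
    stop("exhaustive enumeration is implemented for dichotomous outcomes only")
  } else if (is.finite(A) && A - 1 < B) {
    warning(sprintf(
      "B = %d exceeds the %d distinct non-identity arrangements; %s",
      B, as.integer(A - 1), "Monte-Carlo duplicates will occur"))
  }

  if (doExhaustive) {
    lev2 <- levels(factor(oc))[2L]
    p2 <- which(oc == lev2); p1 <- which(oc != lev2)
    subsets <- utils::combn(n, length(p2))
    obs <- sort(p2)
    isObs <- apply(subsets, 2L, function(s) identical(s, obs))
    subsets <- subsets[, !isObs, drop = FALSE]
    Beff <- ncol(subsets)
    idx <- matrix(0L, Beff + 1L, n)
    idx[1L, ] <- seq_len(n)
    for (b in seq_len(Beff)) {
      row <- integer(n)
      s <- subsets[, b]
      row[s] <- p2
      row[setdiff(seq_len(n), s)] <- p1
      idx[b + 1L, ] <- row
    }
    return(new("PermutationPlan", B = as.integer(Beff),
               seed = as.integer(seed), labelIdx = idx,
               sampleIds = universe, exhaustive = TRUE))
  }

  set.seed(as.integer(seed))
  idx <- matrix(0L, B + 1L, n)
  idx[1L, ] <- seq_len(n)
  for (b in seq_len(B)) idx[b + 1L, ] <- sample.int(n)
  new("PermutationPlan", B = as.integer(B), seed = as.integer(seed),
      labelIdx = idx, sampleIds = universe, exhaustive = FALSE)
}

#' Compute the statistic matrix of one modality over a permutation plan
#'
#' Applies the modality's association statistic under every labelling of
#' the plan (row 0 = observed), restricted to the dataset's own samples.
#' Covariates stay attached to their samples; only the outcome is permuted
#' (`permScheme = "label"`). With `permScheme = "freedman-lane"`,
#' reduced-model residuals are permuted instead, which is more robust under
#' strong covariate effects (linear-model statistics only).
#'
#' Fast vectorized kernels cover the dichotomous, covariate-free case that
#' dominates permutation workloads; general designs fall back to a
#' per-permutation least-squares path. Empirical-Bayes moderation
#' hyperparameters are estimated once on the observed labelling and reused
#' across permutations unless `moderationPerPerm = TRUE`.
#'
#' @param dataset an [OmicsDataset-class]; its samples must be contained in
#'   the plan's universe.
#' @param plan a [PermutationPlan-class].
#' @param design the [StudyDesign-class] the plan was built from.
#' @param spec a [statisticSpec()]; defaults per modality kind.
#' @param permScheme `"label"` or `"freedman-lane"`.
#' @param moderationPerPerm re-estimate moderation hyperparameters for every
#'   permutation (slower; general path only).
#' @return numeric matrix, (B + 1) x features, oriented so that larger
#'   values mean stronger evidence against the partial null; row 1 holds the
#'   observed statistics.
#' @export
computeStatistics <- function(dataset, plan, design, spec = NULL,
                              permScheme = c("label", "freedman-lane"),
                              moderationPerPerm = FALSE) {
  permScheme <- match.arg(permScheme)
  if (is.null(spec)) spec <- defaultStatisticSpec(dataset, design)
  samples <- sampleIds(dataset)
  colIdx <- match(samples, sampleIds(plan))
  if (anyNA(colIdx)) stop(sprintf("dataset '%s' has samples outside the plan universe",
                                  modalityId(dataset)))
  oc <- outcome(design)
  Bp1 <- plan@B + 1L
  # labels[b, j]: outcome assigned to the dataset's j-th sample in permutation b
  labIdx <- plan@labelIdx[, colIdx, drop = FALSE]
  Y <- assayValues(dataset)
  nd <- length(samples)
  dichot <- outcomeType(design) == "dichotomous"
  noCov <- ncol(covariates(design)) == 0L
  meth <- spec$method

  if (meth == "voom_linear_model_t" && modalityKind(dataset) != "counts")
    stop("voom pretreatment is only defined for count data")
  if (meth %in% c("genotype_trend", "ranksum")) {
    if (!dichot) stop(sprintf("%s requires a dichotomous outcome", meth))
    if (!noCov) stop(sprintf("%s does not support covariates", meth))
    if (permScheme != "label") stop(sprintf("%s supports only label permutation", meth))
  }

  if (dichot && noCov && permScheme == "label") {
    lev2 <- levels(oc)[2L]
    isLev2 <- as.numeric(oc == lev2)
    L <- matrix(isLev2[labIdx], Bp1, nd)
    if (meth == "genotype_trend") {
      return(t(.orient(.trendZ(Y, L), spec$sidedness)))
    }
    if (meth == "ranksum") {
      return(t(.orient(.ranksumZ(Y, L), spec$sidedness)))
    }
    W <- NULL
    if (meth == "voom_linear_model_t") {
      dm <- designMatrix(design, oc[samples], samples)
      vt <- voomTransform(dataset, dm$X)
      Y <- vt$logcpm
      W <- vt$weights
    }
    fit <- .twoGroupT(Y, L, W = W,
                      moderation = if (spec$moderation) TRUE else NULL)
    return(t(.orient(fit$t, spec$sidedness)))
  }

  # ---- general path ---------------------------------------------------------
  weights <- NULL
  if (meth == "voom_linear_model_t") {
    dm <- designMatrix(design, oc[samples], samples)
    vt <- voomTransform(dataset, dm$X)
    Y <- vt$logcpm
    weights <- vt$weights
  }
  designSub <- StudyDesign(samples, oc[samples],
                           covariates = covariates(design)[
                             match(samples, sampleIds(design)), , drop = FALSE],
                           outcomeType = outcomeType(design))

  fl <- NULL
  if (permScheme == "freedman-lane") {
    # reduced model: intercept + covariates; residuals are exchangeable under
    # the null of no outcome effect
    covSub <- covariates(designSub)
    Z <- if (ncol(covSub)) stats::model.matrix(~ ., data = covSub)
         else matrix(1, nd, 1L)
    fit0 <- Z %*% qr.coef(qr(Z), t(Y))
    fl <- list(fitted = fit0, resid = t(Y) - fit0)
  }

  out <- matrix(NA_real_, Bp1, nrow(Y),
                dimnames = list(NULL, rownames(Y)))
  mp <- NULL
  for (b in seq_len(Bp1)) {
    if (permScheme == "freedman-lane") {
      Yb <- if (b == 1L) Y else t(fl$fitted + fl$resid[labIdx[b, ], , drop = FALSE])
      labs <- oc[samples]
    } else {
      Yb <- Y
      labs <- oc[labIdx[b, ]]
    }
    st <- linearModelStats(Yb, designSub, spec, outcomeLabels = labs,
                           weights = weights,
                           moderationParams = if (moderationPerPerm) NULL else mp)
    if (b == 1L && spec$moderation) mp <- st$moderationParams
    out[b, ] <- st$statistic
  }
  out
}

#' Pool statistics into partial (pseudo-)p-values
#'
#' Converts a (B + 1) x features statistic matrix into the matrix of
#' partial p-values (row 1, the observed labelling) and pseudo p-values
#' (rows 2..B+1, one per permutation). With the zero-avoidance correction
#' on, every statistic is compared self-inclusively against all B + 1
#' pooled values: `lambda_b = #\{b' in 0..B : T_b' >= T_b\} / (B + 1)`; for
#' the observed row this reproduces the augmented estimator
#' `(1 + #\{b' >= 1 : T_b' >= T_0\}) / (B + 1)`, so no p-value can reach
#' zero and the minimum attainable value is `1/(B + 1)`. With the
#' correction off, statistics are compared against the B permutation rows
#' only (`lambda_b = #\{b' in 1..B : T_b' >= T_b\} / B`), and the observed
#' row can reach zero -- the uncorrected comparison variant.
#'
#' Ties count as exceedances (the `>=` in the indicator), which is
#' conservative.
#'
#' @param statMatrix numeric matrix, (B + 1) x features, larger = stronger
#'   evidence; row 1 is the observed labelling.
#' @param zeroCorrection logical, default TRUE.
#' @return matrix of the same shape with entries in `[1/(B+1), 1]`
#'   (corrected) or `[0, 1]` (uncorrected).
#' @export
poolPValues <- function(statMatrix, zeroCorrection = TRUE) {
  n <- nrow(statMatrix)
  B <- n - 1L
  # compare after rounding to 10 significant digits: relabelings that are
  # mathematically tied (e.g. group swaps of a two-sided statistic) must pool
  # as ties rather than be split by floating-point noise
  statMatrix <- signif(statMatrix, 10L)
  rk <- apply(statMatrix, 2L, rank, ties.method = "min")
  cntAll <- n - rk + 1  # self-inclusive exceedance counts over all B+1 rows
  if (zeroCorrection) {
    lam <- cntAll / n
  } else {
    if (B == 0L) stop("uncorrected pooling requires B >= 1")
    geObs <- sweep(statMatrix, 2L, statMatrix[1L, ], "<=")  # T_b <= T_0
    lam <- (cntAll - geObs) / B
  }
  dimnames(lam) <- dimnames(statMatrix)
  lam
}

#' Specify a combining function
#'
#' @param name `"fisher"`, `"liptak"` or `"tippett"`.
#' @param weights optional positive per-modality weights; normalized to sum
#'   to one. `NULL` gives the unweighted function (all weights 1).
#' @return a list of class `CombinerSpec`.
#' @export
combinerSpec <- function(name = c("fisher", "liptak", "tippett"),
                         weights = NULL) {
  name <- match.arg(name)
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop("combining weights must be positive")
    weights <- weights / sum(weights)
  }
  structure(list(name = name, weights = weights), class = "CombinerSpec")
}

#' Combine partial p-values across modalities
#'
#' Maps the per-modality p-value matrices to the global test statistic, per
#' feature and per permutation row: Fisher
#' `T = -2 * sum_i w_i log(lambda_i)`, Liptak
#' `T = sum_i w_i qnorm(1 - lambda_i)`, Tippett
#' `T = max_i w_i (1 - lambda_i)`. Unweighted combination uses `w_i = 1`
#' for every modality. For Liptak, p-values are clamped symmetrically into
#' `[1/(2(B+1)), 1 - 1/(2(B+1))]` so the normal quantile stays finite when
#' a pooled p-value equals 1 (total ties).
#'
#' @param cube list of (B + 1) x features p-value matrices, one per
#'   modality (all the same shape), as produced by [poolPValues()].
#' @param combiner a [combinerSpec()] (or a combiner name).
#' @param allowZero accept zero p-values (uncorrected pooling): Fisher maps
#'   them to an infinite combined statistic (which still pools by rank),
#'   Liptak's clamp keeps the normal quantile finite. By default zero
#'   p-values are an error pointing at the zero-avoidance correction.
#' @return numeric matrix, (B + 1) x features, of combined statistics
#'   (larger = stronger evidence).
#' @export
combinePValues <- function(cube, combiner = combinerSpec("fisher"),
                           allowZero = FALSE) {
  if (is.character(combiner)) combiner <- combinerSpec(combiner)
  k <- length(cube)
  stopifnot(k >= 1L)
  dims <- dim(cube[[1L]])
  w <- combiner$weights
  if (is.null(w)) w <- rep(1, k)
  if (length(w) != k) stop("one weight per modality is required")
  if (!allowZero && combiner$name %in% c("fisher", "liptak") &&
      any(vapply(cube, function(m) any(m <= 0), logical(1L)))) {
    stop("zero p-values cannot be combined with fisher/liptak; ",
         "enable the zero-avoidance correction")
  }
  Tm <- matrix(0, dims[1L], dims[2L])
  if (combiner$name == "fisher") {
    for (i in seq_len(k)) Tm <- Tm - 2 * w[i] * log(cube[[i]])
  } else if (combiner$name == "liptak") {
    lo <- 1 / (2 * dims[1L])
    for (i in seq_len(k)) {
      lam <- pmin(pmax(cube[[i]], lo), 1 - lo)
      Tm <- Tm + w[i] * stats::qnorm(1 - lam)
    }
  } else {
    Tm <- matrix(-Inf, dims[1L], dims[2L])
    for (i in seq_len(k)) Tm <- pmax(Tm, w[i] * (1 - cube[[i]]))
  }
  dimnames(Tm) <- dimnames(cube[[1L]])
  Tm
}

#' Global p-values from combined statistics
#'
#' Applies the same pooled comparison rule as [poolPValues()] to the B + 1
#' combined statistics of each feature and returns the observed row: the
#' global p-value. With the correction on, global p-values are bounded
#' below by `1/(B + 1)` and can never be zero.
#'
#' @param globalStats (B + 1) x features matrix from [combinePValues()].
#' @param zeroCorrection as in [poolPValues()].
#' @return named numeric vector of per-feature global p-values.
#' @export
globalPValue <- function(globalStats, zeroCorrection = TRUE) {
  poolPValues(globalStats, zeroCorrection)[1L, ]
}

#' Run the full NPC analysis
#'
#' Orchestrates the complete pipeline: optional feature mapping, the
#' synchronized permutation plan, per-modality statistic matrices, pooled
#' partial (pseudo-)p-values, combination across modalities, global
#' p-values, and Benjamini-Hochberg FDR adjustment. The result is
#' deterministic given the inputs, `B` and `seed`.
#'
#' @param datasets list of [OmicsDataset-class] objects with unique
#'   modality ids; samples must be contained in the design universe.
#' @param design a [StudyDesign-class].
#' @param mapping optional [FeatureMapping-class] applied first.
#' @param specs optional named list of [statisticSpec()]s keyed by modality
#'   id; missing entries use [defaultStatisticSpec()].
#' @param combiners character vector of combining functions to apply.
#' @param B number of permutations (default 1000; permutation p-values have
#'   granularity `1/(B+1)`, so analyses at genome scale typically use
#'   10000).
#' @param seed RNG seed for the permutation plan.
#' @param zeroCorrection apply the zero-avoidance correction (default TRUE;
#'   FALSE gives the uncorrected comparison variant).
#' @param weights optional positive per-modality combination weights.
#' @param permScheme passed to [computeStatistics()].
#' @param keepUnmapped passed to [applyMapping()].
#' @param exhaustive passed to [buildPermutationPlan()].
#' @param verbose log progress to stderr.
#' @return an [NPCResult-class].
#' @examples
#' study <- assembleScenario("correlated_modalities", nGenes = 60,
#'                           samplesPerGroup = 5, deCount = 20, rho = 0.8,
#'                           seed = 1)
#' res <- runNPC(studyDatasets(study), studyDesign(study), B = 99, seed = 2)
#' head(resultTable(res))
#' @export
runNPC <- function(datasets, design, mapping = NULL, specs = NULL,
                   combiners = c("fisher", "liptak", "tippett"),
                   B = 1000L, seed = 1L, zeroCorrection = TRUE,
                   weights = NULL, permScheme = "label",
                   keepUnmapped = FALSE, exhaustive = "auto",
                   verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  checkSampleUniverse(datasets, design)
  mids <- vapply(datasets, modalityId, character(1L))
  if (anyDuplicated(mids)) stop("duplicate modality ids")
  names(datasets) <- mids
  if (!is.null(mapping)) {
    datasets <- applyMapping(datasets, mapping, keepUnmapped = keepUnmapped)
    mids <- vapply(datasets, modalityId, character(1L))
    names(datasets) <- mids
  }
  common <- Reduce(intersect, lapply(datasets, featureIds))
  if (!length(common)) stop("no feature groups shared across all modalities")
  dropped <- sum(vapply(datasets, function(d) length(featureIds(d)), 0L)) -
             length(common) * length(datasets)
  if (dropped > 0L) {
    say("runNPC: %d feature rows not shared across all modalities dropped", dropped)
  }
  datasets <- lapply(datasets, function(d) {
    OmicsDataset(assayValues(d)[common, , drop = FALSE], modalityKind(d),
                 modalityId(d))
  })

  plan <- buildPermutationPlan(design, B = B, seed = seed,
                               exhaustive = exhaustive)
  say("runNPC: plan with B = %d (%s), %d modalities, %d feature groups",
      plan@B, if (plan@exhaustive) "exhaustive" else "sampled",
      length(datasets), length(common))

  statList <- lapply(datasets, function(d) {
    sp <- if (!is.null(specs) && modalityId(d) %in% names(specs))
            specs[[modalityId(d)]] else defaultStatisticSpec(d, design)
    say("runNPC: modality '%s' -> %s%s", modalityId(d), sp$method,
        if (sp$moderation) " (moderated)" else "")
    computeStatistics(d, plan, design, sp, permScheme = permScheme)
  })
  cube <- lapply(statList, poolPValues, zeroCorrection = zeroCorrection)

  tb <- data.frame(group_id = common, stringsAsFactors = FALSE)
  for (i in seq_along(cube)) {
    tb[[paste0("pvalue_partial_", mids[i])]] <- cube[[i]][1L, ]
  }
  for (cmb in combiners) {
    gs <- combinePValues(cube, combinerSpec(cmb, weights),
                         allowZero = !zeroCorrection)
    tb[[paste0("pvalue_global_", cmb)]] <- globalPValue(gs, zeroCorrection)
  }
  for (i in seq_along(cube)) {
    tb[[paste0("fdr_partial_", mids[i])]] <-
      stats::p.adjust(tb[[paste0("pvalue_partial_", mids[i])]], "BH")
  }
  for (cmb in combiners) {
    tb[[paste0("fdr_global_", cmb)]] <-
      stats::p.adjust(tb[[paste0("pvalue_global_", cmb)]], "BH")
  }
  rownames(tb) <- NULL
  new("NPCResult", table = tb, B = plan@B, seed = as.integer(seed),
      combiners = combiners, modalities = unname(mids),
      zeroCorrection = zeroCorrection)
}
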