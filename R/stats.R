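#' Specify an association statistic for one modality
#'
#' Describes which per-feature association statistic to use for a modality,
#' whether to apply empirical-Bayes variance moderation, and the test
#' sidedness. The default mapping from modality kind is: counts ->
#' `voom_linear_model_t` (log-CPM transform with precision weights, then a
#' moderated t), continuous -> `linear_model_t` (moderated t; a partial F
#' when the outcome is multiclass), genotype -> `genotype_trend`
#' (Cochran-Armitage trend test), uniform_like -> `ranksum` (Wilcoxon
#' rank-sum, one-sided towards larger values in the second group).
#'
#' @param method one of `"linear_model_t"`, `"linear_model_F"`,
#'   `"voom_linear_model_t"`, `"genotype_trend"`, `"ranksum"`.
#' @param moderation logical; shrink per-feature residual variances towards
#'   a common prior (empirical Bayes). Ignored for trend and rank-sum
#'   statistics.
#' @param sidedness `"two_sided"`, `"one_sided_greater"` or
#'   `"one_sided_less"`; one-sided directions refer to the second outcome
#'   level (or a positive slope for continuous outcomes).
#' @return a list of class `StatisticSpec`.
#' @export
statisticSpec <- function(method = c("linear_model_t", "linear_model_F",
                                     "voom_linear_model_t", "genotype_trend",
                                     "ranksum"),
                          moderation = TRUE,
                          sidedness = c("two_sided", "one_sided_greater",
                                        "one_sided_less")) {
  structure(list(method = match.arg(method), moderation = isTRUE(moderation),
                 sidedness = match.arg(sidedness)),
            class = "StatisticSpec")
}

#' Default statistic specification for a dataset
#'
#' @param dataset an [OmicsDataset-class].
#' @param design a [StudyDesign-class]; a multiclass outcome selects the
#'   partial F statistic for linear-model methods.
#' @return a `StatisticSpec`.
#' @export
defaultStatisticSpec <- function(dataset, design) {
  kind <- modalityKind(dataset)
  multi <- outcomeType(design) == "multiclass"
  switch(kind,
    counts = statisticSpec("voom_linear_model_t", moderation = TRUE),
    continuous = statisticSpec(if (multi) "linear_model_F" else "linear_model_t",
                               moderation = TRUE),
    genotype = statisticSpec("genotype_trend", moderation = FALSE),
    uniform_like = statisticSpec("ranksum", moderation = FALSE,
                                 sidedness = "one_sided_greater"))
}

#' Build the model matrix for an outcome labelling
#'
#' Constructs an intercept + outcome (+ covariates) model matrix,
#' identifying the columns that encode the outcome. Categorical covariates
#' are expanded to indicator columns. A rank-deficient matrix (e.g. a
#' constant covariate, or an outcome collinear with the covariates) is an
#' error.
#'
#' @param design a [StudyDesign-class] restricted to the samples being
#'   modelled (covariates are taken from it).
#' @param outcomeLabels per-sample outcome values (possibly permuted),
#'   aligned with `samples`.
#' @param samples sample ids the rows refer to.
#' @return list with `X` (the model matrix), `outcomeCols` (column indices
#'   of the outcome terms) and `df` (residual degrees of freedom).
#' @export
designMatrix <- function(design, outcomeLabels, samples = sampleIds(design)) {
  cov <- covariates(design)[match(samples, sampleIds(design)), , drop = FALSE]
  oc <- if (outcomeType(design) == "continuous") as.numeric(outcomeLabels)
        else factor(outcomeLabels)
  df <- data.frame(.outcome = oc, cov, check.names = FALSE)
  X <- stats::model.matrix(~ ., data = df)
  ocCols <- grep("^\\.outcome", colnames(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop(sprintf("rank-deficient design (rank %d < %d columns): %s",
                 qrX$rank, ncol(X),
                 "check for constant or collinear covariates"))
  }
  list(X = X, outcomeCols = ocCols, df = nrow(X) - ncol(X))
}

# ---- internal vectorized kernels -------------------------------------------
# All kernels take Y (features x n) and L ((B+1) x n 0/1 membership of the
# second outcome level) and return a features x (B+1) statistic matrix.
# Orientation guarantees of the public wrappers: larger = stronger evidence.

.SENTINEL <- 1e150  # stands in for an infinite statistic (zero residual variance)

# ordinary / moderated two-group t, optionally weighted (gene x sample W)
.twoGroupT <- function(Y, L, W = NULL, moderation = NULL) {
  n <- ncol(Y)
  n2 <- rowSums(L); n1 <- n - n2
  if (any(n2 == 0L | n1 == 0L)) stop("a permutation leaves one group empty")
  dfres <- n - 2L
  if (is.null(W)) {
    S2 <- Y %*% t(L)
    S <- rowSums(Y); Q <- rowSums(Y * Y)
    m2 <- sweep(S2, 2L, n2, "/")
    m1 <- sweep(S - S2, 2L, n1, "/")
    RSS <- Q - sweep(m1 * m1, 2L, n1, "*") - sweep(m2 * m2, 2L, n2, "*")
    RSS[RSS < 1e-20 * pmax(1, Q)] <- 0  # zero residual variance, exactly
    beta <- m2 - m1
    cfac <- 1 / n1 + 1 / n2
    varScale <- matrix(cfac, nrow(Y), length(cfac), byrow = TRUE)
  } else {
    WY <- W * Y
    Sw <- rowSums(W); Swy <- rowSums(WY); Swyy <- rowSums(WY * Y)
    Swx <- W %*% t(L)
    Swxy <- WY %*% t(L)
    D <- Sw * Swx - Swx * Swx
    D[D <= 0] <- NA_real_
    beta <- (Sw * Swxy - Swx * Swy) / D
    b0 <- (Swy - beta * Swx) / Sw
    RSS <- Swyy - b0 * Swy - beta * Swxy
    RSS[RSS < 1e-20 * pmax(1, Swyy)] <- 0
    # WLS residual df equals n - 2 (weights known, not estimated)
    varScale <- Sw / D
  }
  s2 <- RSS / dfres
  dfTot <- dfres
  if (isTRUE(moderation)) {
    # hyperparameters from the observed labelling (column 1), reused for all
    # permuted relabelings
    moderation <- estimateModeration(s2[, 1L], dfres)
  }
  if (is.list(moderation)) {
    d0 <- moderation$d0; s02 <- moderation$s02
    s2 <- if (is.infinite(d0)) matrix(s02, nrow(s2), ncol(s2))
          else (d0 * s02 + dfres * s2) / (d0 + dfres)
    dfTot <- dfres + d0
  }
  tt <- beta / sqrt(s2 * varScale)
  tt[!is.finite(tt) & beta > 0] <- .SENTINEL
  tt[!is.finite(tt) & beta < 0] <- -.SENTINEL
  tt[!is.finite(tt)] <- 0  # zero-variance, zero-effect features
  list(t = tt, df = dfTot, moderation = if (is.list(moderation)) moderation)
}

# Cochran-Armitage trend z via the N * r^2 identity (scores 0/1/2)
.trendZ <- function(Y, L) {
  n <- ncol(Y)
  n2 <- rowSums(L)
  Sg <- rowSums(Y); Sgg <- rowSums(Y * Y)
  Sgx <- Y %*% t(L)
  num <- n * Sgx - outer(Sg, n2)
  den2 <- outer(n * Sgg - Sg * Sg, n * n2 - n2 * n2)
  den2[den2 <= 0] <- NA_real_
  z <- sqrt(n) * num / sqrt(den2)
  z[!is.finite(z)] <- 0  # monomorphic SNPs
  z
}

# Wilcoxon rank-sum z (midranks, tie-corrected variance, no continuity corr.)
.ranksumZ <- function(Y, L) {
  n <- ncol(Y)
  n2 <- rowSums(L); n1 <- n - n2
  R <- t(apply(Y, 1L, rank))           # midranks, per feature
  W2 <- R %*% t(L)                     # rank sum of the second group
  E <- n2 * (n + 1) / 2
  tieTerm <- apply(Y, 1L, function(y) {
    tt <- table(y); sum(tt^3 - tt)
  })
  v <- outer(rep(1, nrow(Y)), n1 * n2 * (n + 1) / 12) -
       outer(tieTerm, n1 * n2 / (12 * n * (n - 1)))
  v[v <= 0] <- NA_real_
  z <- sweep(W2, 2L, E, "-") / sqrt(v)
  z[!is.finite(z)] <- 0  # fully tied features
  z
}

.orient <- function(stat, sidedness) {
  switch(sidedness,
         two_sided = abs(stat),
         one_sided_greater = stat,
         one_sided_less = -stat)
}

# ---- moderation hyperparameters --------------------------------------------

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Fits a scaled-F model to the per-feature residual variances (via
#' moment matching of log variances, as implemented by
#' `limma::fitFDist`), yielding the prior degrees of freedom `d0` and the
#' prior variance `s02` used to moderate t-statistics:
#' `s2_tilde = (d0 * s02 + df * s2) / (d0 + df)`.
#'
#' @param s2 per-feature residual variances.
#' @param df residual degrees of freedom they were computed with.
#' @return list with elements `d0` and `s02` (`d0` may be `Inf`).
#' @export
estimateModeration <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 3L) {
    return(list(d0 = 0, s02 = if (length(s2)) stats::median(s2) else 1))
  }
  fit <- limma::fitFDist(s2, df1 = df)
  list(d0 = fit$df2, s02 = fit$scale)
}

# ---- voom ------------------------------------------------------------------

#' Log-CPM transform with precision weights for count data
#'
#' Pretreats sequencing counts for linear modelling: computes
#' `log2((count + 0.5) / (libsize + 1) * 1e6)` and derives per-observation
#' precision weights from the mean-variance trend (a lowess fit of the
#' square-root residual standard deviation against the average log count),
#' as implemented by `limma::voom`. Downstream linear-model statistics use
#' weighted least squares with these weights.
#'
#' @param counts an [OmicsDataset-class] with `kind = "counts"` (or a plain
#'   count matrix).
#' @param designMat model matrix used to estimate the mean-variance trend
#'   (typically the observed-labels design).
#' @return list with `logcpm` (features x samples), `weights` (same shape,
#'   strictly positive) and `libSize`.
#' @export
voomTransform <- function(counts, designMat) {
  m <- if (is(counts, "OmicsDataset")) assayValues(counts) else counts
  lib <- colSums(m)
  if (any(lib == 0)) stop("sample(s) with zero total counts: ",
                          paste(colnames(m)[lib == 0], collapse = ", "))
  v <- tryCatch(limma::voom(m, design = designMat), error = function(e) NULL)
  if (is.null(v)) {
    # degenerate mean-variance trend (e.g. a single distinct mean count):
    # the log-CPM transform is still defined, and with no trend to estimate
    # every observation carries equal precision
    logcpm <- log2(t((t(m) + 0.5) / (lib + 1)) * 1e6)
    return(list(logcpm = logcpm,
                weights = matrix(1, nrow(m), ncol(m), dimnames = dimnames(m)),
                libSize = lib))
  }
  list(logcpm = v$E, weights = v$weights, libSize = lib)
}

# ---- public per-modality statistic functions -------------------------------

#' Per-feature linear-model statistics
#'
#' Fits `y ~ outcome (+ covariates)` per feature by (weighted) least
#' squares and returns the outcome t-statistic (or the partial F over the
#' outcome's indicator columns for a multiclass outcome). With
#' `moderation`, per-feature variances are shrunk towards the
#' empirical-Bayes prior and the degrees of freedom increase by the prior
#' `d0`. Features with zero residual variance and a non-zero effect receive
#' a large sentinel value and are flagged; all-constant features receive
#' statistic 0.
#'
#' @param dataset an [OmicsDataset-class] (or matrix of values; for counts
#'   pass the log-CPM from [voomTransform()] together with its `weights`).
#' @param design a [StudyDesign-class].
#' @param spec a [statisticSpec()].
#' @param outcomeLabels optional replacement outcome (e.g. permuted labels)
#'   aligned with the dataset's samples; defaults to the observed outcome.
#' @param weights optional features x samples precision weights.
#' @param moderationParams optional list `(d0, s02)`; when missing and
#'   `spec$moderation` is TRUE, estimated from this data.
#' @return list with `statistic` (oriented so that larger = stronger
#'   evidence), `raw` (the signed t or F), `df`, and `flagged` (logical:
#'   zero-residual-variance features).
#' @export
linearModelStats <- function(dataset, design, spec = statisticSpec(),
                             outcomeLabels = NULL, weights = NULL,
                             moderationParams = NULL) {
  Y <- if (is(dataset, "OmicsDataset")) assayValues(dataset) else dataset
  samples <- colnames(Y)
  if (is.null(outcomeLabels)) outcomeLabels <- outcome(design)[samples]
  dm <- designMatrix(design, outcomeLabels, samples)
  if (nrow(dm$X) <= ncol(dm$X)) stop("more model columns than samples")
  fit <- .lmStatsOneLabelling(Y, dm, weights = weights,
                              moderation = spec$moderation,
                              moderationParams = moderationParams,
                              useF = spec$method == "linear_model_F" ||
                                     outcomeType(design) == "multiclass")
  stat <- if (fit$isF) fit$raw else .orient(fit$raw, spec$sidedness)
  list(statistic = stat, raw = fit$raw, df = fit$df,
       flagged = fit$flagged, moderationParams = fit$moderationParams)
}

# single-labelling (weighted) least squares across features; general designs
.lmStatsOneLabelling <- function(Y, dm, weights = NULL, moderation = TRUE,
                                 moderationParams = NULL, useF = FALSE) {
  X <- dm$X
  n <- nrow(X); p <- ncol(X)
  dfres <- n - p
  G <- nrow(Y)
  if (is.null(weights)) {
    qrX <- qr(X)
    coefs <- qr.coef(qrX, t(Y))
    res <- t(Y) - X %*% coefs
    RSS <- colSums(res * res)
    XtXinv <- chol2inv(qr.R(qrX))
    if (useF) {
      oc <- dm$outcomeCols
      Xr <- X[, -oc, drop = FALSE]
      RSS0 <- colSums((t(Y) - Xr %*% qr.coef(qr(Xr), t(Y)))^2)
      beta <- NULL
      cfac <- NULL
    } else {
      k <- dm$outcomeCols[1L]
      beta <- coefs[k, ]
      cfac <- XtXinv[k, k]
    }
  } else {
    # gene-wise weights: per-feature WLS solves (small p, loop over features)
    RSS <- numeric(G); beta <- numeric(G); cfac <- numeric(G)
    RSS0 <- numeric(G)
    oc <- dm$outcomeCols
    for (g in seq_len(G)) {
      w <- weights[g, ]
      A <- crossprod(X * w, X)
      Ai <- solve(A)
      bg <- Ai %*% crossprod(X * w, Y[g, ])
      rg <- Y[g, ] - X %*% bg
      RSS[g] <- sum(w * rg * rg)
      beta[g] <- bg[oc[1L]]
      cfac[g] <- Ai[oc[1L], oc[1L]]
      if (useF) {
        Xr <- X[, -oc, drop = FALSE]
        br <- solve(crossprod(Xr * w, Xr), crossprod(Xr * w, Y[g, ]))
        r0 <- Y[g, ] - Xr %*% br
        RSS0[g] <- sum(w * r0 * r0)
      }
    }
  }
  RSS[RSS < 0] <- 0
  # flag zero residual variance (perfect separation / constant features);
  # threshold relative to the feature's total sum of squares
  flagged <- RSS <= 1e-20 * pmax(1, rowSums(Y * Y))
  RSS[flagged] <- 0
  s2 <- RSS / dfres
  mp <- NULL
  dfTot <- dfres
  if (moderation) {
    mp <- if (is.null(moderationParams)) estimateModeration(s2, dfres)
          else moderationParams
    s2 <- if (is.infinite(mp$d0)) rep(mp$s02, G)
          else (mp$d0 * mp$s02 + dfres * s2) / (mp$d0 + dfres)
    dfTot <- dfres + mp$d0
  }
  if (useF) {
    q <- length(dm$outcomeCols)
    Fv <- ((RSS0 - RSS) / q) / s2
    Fv[!is.finite(Fv) & RSS0 > RSS] <- .SENTINEL
    Fv[!is.finite(Fv)] <- 0
    Fv[Fv < 0] <- 0
    list(raw = Fv, df = c(q, dfTot), flagged = flagged, isF = TRUE,
         moderationParams = mp)
  } else {
    tt <- beta / sqrt(s2 * cfac)
    tt[!is.finite(tt) & beta > 0] <- .SENTINEL
    tt[!is.finite(tt) & beta < 0] <- -.SENTINEL
    tt[!is.finite(tt)] <- 0
    list(raw = tt, df = dfTot, flagged = flagged, isF = FALSE,
         moderationParams = mp)
  }
}

#' Cochran-Armitage trend statistic per SNP
#'
#' Tests association between genotype dosage (scores 0, 1, 2) and a
#' dichotomous outcome with the Cochran-Armitage trend test, computed via
#' the identity chi-square = N * r^2 between dosage and group indicator.
#' Monomorphic SNPs receive statistic 0 and are flagged.
#'
#' @param dataset an [OmicsDataset-class] with `kind = "genotype"` (or a
#'   dosage matrix).
#' @param groups per-sample dichotomous labels aligned with the dataset's
#'   samples.
#' @param sidedness as in [statisticSpec()]; the signed z is positive when
#'   dosage increases in the second group level.
#' @return list with `statistic` (oriented), `z` (signed), and `flagged`.
#' @export
genotypeTrendStat <- function(dataset, groups, sidedness = "two_sided") {
  Y <- if (is(dataset, "OmicsDataset")) assayValues(dataset) else dataset
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("genotype trend test requires a dichotomous outcome")
  L <- matrix(as.numeric(g == levels(g)[2L]), nrow = 1L)
  z <- .trendZ(Y, L)[, 1L]
  list(statistic = .orient(z, sidedness), z = z,
       flagged = apply(Y, 1L, function(r) length(unique(r)) == 1L))
}

#' Wilcoxon rank-sum statistic per feature
#'
#' Computes the rank-sum W of the first group level (with midranks for
#' ties) and the tie-corrected normal standardization z of the second
#' group's rank sum. The oriented statistic is z (one-sided) or |z|
#' (two-sided); `one_sided_greater` detects larger values in the second
#' group level.
#'
#' @param dataset an [OmicsDataset-class] or numeric matrix.
#' @param groups per-sample dichotomous labels aligned with the dataset's
#'   samples.
#' @param sidedness as in [statisticSpec()].
#' @return list with `statistic` (oriented), `z`, and `W` (rank sum of the
#'   first group level).
#' @export
ranksumStat <- function(dataset, groups, sidedness = "two_sided") {
  Y <- if (is(dataset, "OmicsDataset")) assayValues(dataset) else dataset
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("rank-sum test requires a dichotomous outcome")
  if (any(table(g) == 0L)) stop("empty group")
  L <- matrix(as.numeric(g == levels(g)[2L]), nrow = 1L)
  z <- .ranksumZ(Y, L)[, 1L]
  R <- t(apply(Y, 1L, rank))
  W1 <- R %*% (1 - t(L))
  list(statistic = .orient(z, sidedness), z = z, W = W1[, 1L])
}

# ---- parametric per-modality p-values (for CP / Benjamini / single-modality)

#' Parametric per-feature p-values for one modality
#'
#' Analyses one dataset in isolation with its modality-appropriate
#' statistic and returns classical parametric p-values: t (moderated by
#' default) or F distributions for linear models (voom-pretreated for
#' counts), the chi-square(1) trend test for genotypes, and the
#' normal-approximation Wilcoxon rank-sum for uniform-like data. These are
#' the partial p-values consumed by the parametric combination (CP) and
#' Benjamini partial-conjunction comparison methods, and the
#' single-modality baselines of the benchmark.
#'
#' @param dataset an [OmicsDataset-class].
#' @param design a [StudyDesign-class].
#' @param spec optional [statisticSpec()]; defaults per modality kind.
#' @return numeric vector of p-values, named by feature.
#' @export
parametricPValues <- function(dataset, design, spec = NULL) {
  if (is.null(spec)) spec <- defaultStatisticSpec(dataset, design)
  samples <- sampleIds(dataset)
  oc <- outcome(design)[samples]
  meth <- spec$method
  if (meth %in% c("linear_model_t", "linear_model_F", "voom_linear_model_t")) {
    weights <- NULL
    Y <- assayValues(dataset)
    if (meth == "voom_linear_model_t") {
      if (modalityKind(dataset) != "counts")
        stop("voom pretreatment is only defined for count data")
      dm <- designMatrix(design, oc, samples)
      vt <- voomTransform(dataset, dm$X)
      Y <- vt$logcpm
      weights <- vt$weights
    }
    st <- linearModelStats(Y, design, spec, weights = weights)
    if (length(st$df) == 2L) {  # partial F
      p <- stats::pf(st$raw, st$df[1L], st$df[2L], lower.tail = FALSE)
    } else {
      p <- switch(spec$sidedness,
        two_sided = 2 * stats::pt(-abs(st$raw), st$df),
        one_sided_greater = stats::pt(st$raw, st$df, lower.tail = FALSE),
        one_sided_less = stats::pt(st$raw, st$df))
    }
  } else if (meth == "genotype_trend") {
    st <- genotypeTrendStat(dataset, oc, spec$sidedness)
    p <- switch(spec$sidedness,
      two_sided = stats::pchisq(st$z^2, df = 1L, lower.tail = FALSE),
      one_sided_greater = stats::pnorm(st$z, lower.tail = FALSE),
      one_sided_less = stats::pnorm(st$z))
  } else {  # ranksum
    st <- ranksumStat(dataset, oc, spec$sidedness)
    p <- switch(spec$sidedness,
      two_sided = 2 * stats::pnorm(-abs(st$z)),
      one_sided_greater = stats::pnorm(st$z, lower.tail = FALSE),
      one_sided_less = stats::pnorm(st$z))
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  stats::setNames(p, featureIds(dataset))
}
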