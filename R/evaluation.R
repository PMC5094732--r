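#' ROC curve vertices from p-value scores
#'
#' Builds the ROC curve of a scoring (p-values; smaller = stronger
#' evidence) against a ground-truth indicator. Thresholds sweep the
#' distinct score values in ascending order and tied scores are grouped
#' into a single vertex, so an all-tied scoring yields the two-point
#' diagonal. The curve starts at (0, 0) and ends at (1, 1).
#'
#' @param scores numeric vector of per-feature p-values (or any score with
#'   smaller = stronger).
#' @param truth logical (or 0/1) vector of true deregulation indicators;
#'   must contain at least one positive and one negative.
#' @return data.frame with columns `fpr` and `tpr`.
#' @export
rocPoints <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("truth must contain at least one positive and one negative")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  nPos <- sum(truth); nNeg <- sum(!truth)
  ord <- order(scores)
  s <- scores[ord]; tr <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tr); fp <- cumsum(!tr)
  last <- !duplicated(grp, fromLast = TRUE)  # last index within each tie group
  data.frame(fpr = c(0, fp[last] / nNeg), tpr = c(0, tp[last] / nPos))
}

#' McClish-standardized partial AUC over a high-specificity range
#'
#' Integrates the ROC curve (trapezoidal rule, with linear interpolation at
#' the region boundaries) over false-positive rates in
#' `[1 - specHi, 1 - specLo]` -- by default specificity in `[0.9, 1]`, i.e.
#' FPR in `[0, 0.1]` -- and standardizes the raw area with the McClish
#' formula: with `a = 1 - specHi`, `b = 1 - specLo`, the minimum
#' (chance-level) area is `(b^2 - a^2)/2`, the maximum is `b - a`, and the
#' standardized value is `0.5 * (1 + (pAUC - min) / (max - min))`. Chance
#' ordering therefore scores exactly 0.5 and a perfect ranking scores 1,
#' matching the interpretation of the full-range AUC.
#'
#' @param scores,truth as in [rocPoints()].
#' @param specLo,specHi specificity range, `0 <= specLo < specHi <= 1`.
#' @return list with `standardized`, `raw`, and the integration range.
#' @examples
#' paucMcclish(rep(0.5, 100), rep(c(TRUE, FALSE), 50))$standardized  # 0.5
#' @export
paucMcclish <- function(scores, truth, specLo = 0.9, specHi = 1.0) {
  if (!(specLo < specHi) || specLo < 0 || specHi > 1) {
    stop("require 0 <= specLo < specHi <= 1")
  }
  a <- 1 - specHi; b <- 1 - specLo
  roc <- rocPoints(scores, truth)
  raw <- .trapezoidOnRange(roc$fpr, roc$tpr, a, b)
  minArea <- (b^2 - a^2) / 2
  maxArea <- b - a
  std <- 0.5 * (1 + (raw - minArea) / (maxArea - minArea))
  list(standardized = std, raw = raw, fprRange = c(a, b))
}

# trapezoidal integral of the piecewise-linear curve (x, y) over [a, b]
.trapezoidOnRange <- function(x, y, a, b) {
  interp <- function(x0) stats::approx(x, y, xout = x0, ties = max,
                                       rule = 2)$y
  inside <- x > a & x < b
  xs <- c(a, x[inside], b)
  ys <- c(interp(a), y[inside], interp(b))
  sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2)
}

#' Median-pAUC benchmark with paired Wilcoxon comparisons
#'
#' Repeats the full pipeline -- simulate a study, run every method on the
#' identical datasets, score each method's p-values against the ground
#' truth with the standardized partial AUC -- and summarizes each method by
#' its median pAUC across repetitions. Because all methods see the same
#' simulated data in each repetition, the best-performing method (largest
#' median) is compared against every other with a paired two-sided
#' Wilcoxon signed-rank test.
#'
#' @param scenarioFun function(repetition seed) returning a
#'   [SimulatedStudy-class]; see [assembleScenario()].
#' @param methods character vector of method names for [runIntegration()],
#'   or a named list of functions `f(datasets, design, seed)` returning
#'   per-feature p-values.
#' @param repetitions number of simulate/score repetitions (default 20).
#' @param seed base seed; repetition r uses `seed + r` for the simulation
#'   and the analysis.
#' @param subset `"all"` scores every gene; `"common"` restricts scoring to
#'   genes with the same behaviour in all modalities (deregulated in every
#'   modality, or in none).
#' @param B permutations per analysis.
#' @param specLo,specHi pAUC specificity range.
#' @return list with `medians` (named vector), `wilcoxonP` (named vector of
#'   p-values vs the best method, NA for the best itself), `paucs`
#'   (repetitions x methods matrix) and `best`.
#' @export
medianPaucExperiment <- function(scenarioFun, methods, repetitions = 20L,
                                 seed = 1L, subset = c("all", "common"),
                                 B = 1000L, specLo = 0.9, specHi = 1.0) {
  subset <- match.arg(subset)
  stopifnot(repetitions >= 2L)
  methodNames <- if (is.list(methods)) names(methods) else methods
  paucs <- matrix(NA_real_, repetitions, length(methodNames),
                  dimnames = list(NULL, methodNames))
  for (r in seq_len(repetitions)) {
    repSeed <- as.integer(seed) + r
    study <- scenarioFun(repSeed)
    truth <- groundTruth(study)
    anyDe <- rowSums(truth) > 0L
    allDe <- rowSums(truth) == ncol(truth)
    keep <- if (subset == "common") allDe | !anyDe else rep(TRUE, nrow(truth))
    label <- if (subset == "common") allDe[keep] else anyDe[keep]
    pv <- if (is.list(methods)) {
      vapply(methods, function(f)
        f(studyDatasets(study), studyDesign(study), repSeed),
        numeric(nrow(truth)))
    } else {
      runIntegration(studyDatasets(study), studyDesign(study),
                     methods = methods, B = B, seed = repSeed)
    }
    for (m in methodNames) {
      pm <- tryCatch(
        paucMcclish(pv[keep, m], label, specLo, specHi)$standardized,
        error = function(e) {
          warning(sprintf("repetition %d, method %s failed: %s",
                          r, m, conditionMessage(e)))
          NA_real_
        })
      paucs[r, m] <- pm
    }
  }
  med <- apply(paucs, 2L, stats::median, na.rm = TRUE)
  best <- names(which.max(med))
  wp <- stats::setNames(rep(NA_real_, length(methodNames)), methodNames)
  for (m in setdiff(methodNames, best)) {
    ok <- stats::complete.cases(paucs[, c(best, m)])
    d <- paucs[ok, best] - paucs[ok, m]
    wp[m] <- if (all(d == 0)) 1
             else suppressWarnings(
               stats::wilcox.test(paucs[ok, best], paucs[ok, m],
                                  paired = TRUE)$p.value)
  }
  list(medians = med, wilcoxonP = wp, paucs = paucs, best = best)
}

#' Joint null criterion via the double Kolmogorov-Smirnov test
#'
#' Assesses whether a method produces jointly uniform p-values when every
#' null hypothesis is true. Each repetition simulates two complete-null
#' microarray-like datasets over the same samples (independent noise in the
#' `"uncorrelated"` scenario; identical noise, i.e. correlation 1, in the
#' `"correlated"` one), randomly splits the samples into two equal groups,
#' runs the method, and records the two-sided KS p-value of the per-gene
#' p-values against Uniform(0,1). The first-level KS p-values from all
#' repetitions are then themselves tested against Uniform(0,1) with a
#' second KS test, giving the "dks" p-value: calibrated methods yield a
#' non-significant dks p-value.
#'
#' Permutation p-values live on the grid `1/(B+1), ..., 1`, which makes the
#' continuous-uniform KS test slightly conservative; `B` should therefore
#' be at least about 200 so the granularity stays below the KS resolution
#' at the gene counts used here.
#'
#' @param method a method name for [runIntegration()], a character vector
#'   of names (evaluated on shared simulations), or a function
#'   `f(datasets, design, seed)` returning per-gene p-values (or a named
#'   list of such vectors, one report per component).
#' @param repetitions number of first-level repetitions.
#' @param genes number of genes per simulated dataset.
#' @param samples total number of samples (split equally).
#' @param scenario `"uncorrelated"` or `"correlated"`.
#' @param seed base seed; repetition r derives its simulation and analysis
#'   seed from it.
#' @param B permutations for permutation-based methods.
#' @return a [JNCReport-class], or a named list of reports when the method
#'   argument yields several p-value sets.
#' @export
doubleKS <- function(method, repetitions = 1000L, genes = 1000L,
                     samples = 20L, scenario = c("uncorrelated", "correlated"),
                     seed = 1L, B = 200L) {
  scenario <- match.arg(scenario)
  if (samples %% 2L) stop("samples must be even (equal split)")
  methodFun <- method
  label <- "custom"
  if (is.character(method)) {
    label <- paste(method, collapse = ",")
    methodFun <- function(datasets, design, s) {
      pv <- runIntegration(datasets, design, methods = method, B = B, seed = s)
      if (ncol(pv) == 1L) pv[, 1L] else as.list(as.data.frame(pv))
    }
  }
  first <- NULL
  for (r in seq_len(repetitions)) {
    repSeed <- as.integer(seed) + 104729L * (r %% 1000L) + r %/% 1000L
    sim <- .simulateJointNull(genes, samples, scenario, repSeed)
    pv <- methodFun(sim$datasets, sim$design, repSeed)
    if (!is.list(pv)) pv <- list(p = pv)
    ks <- vapply(pv, function(p)
      suppressWarnings(stats::ks.test(p, "punif")$p.value), numeric(1L))
    if (is.null(first)) {
      first <- matrix(NA_real_, repetitions, length(ks),
                      dimnames = list(NULL, names(pv)))
    }
    first[r, ] <- ks
  }
  reports <- lapply(colnames(first), function(cn) {
    dks <- suppressWarnings(stats::ks.test(first[, cn], "punif")$p.value)
    new("JNCReport", firstLevel = first[, cn], dksP = dks,
        repetitions = as.integer(repetitions), scenario = scenario,
        method = if (ncol(first) > 1L) cn else label)
  })
  names(reports) <- colnames(first)
  if (length(reports) == 1L) reports[[1L]] else reports
}

# two complete-null continuous datasets over the same random equal split
.simulateJointNull <- function(genes, samples, scenario, seed) {
  set.seed(seed)
  perGroup <- samples %/% 2L
  sid <- sprintf("s%03d", seq_len(samples))
  grp <- rep("g1", samples)
  grp[sample.int(samples, perGroup)] <- "g2"
  design <- StudyDesign(sid, grp, outcomeType = "dichotomous")
  X <- matrix(stats::rnorm(genes * samples), genes, samples,
              dimnames = list(sprintf("gene%04d", seq_len(genes)), sid))
  Y <- if (scenario == "correlated") X
       else matrix(stats::rnorm(genes * samples), genes, samples,
                   dimnames = dimnames(X))
  list(datasets = list(OmicsDataset(X, "continuous", "micro1"),
                       OmicsDataset(Y, "continuous", "micro2")),
       design = design)
}
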