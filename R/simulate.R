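#' Simulate a microarray-like continuous dataset
#'
#' Non-deregulated genes are iid standard normal across samples.
#' Deregulated genes receive an additive mean shift in the second group:
#' per gene, an effect size delta drawn Uniform(deltaRange[1],
#' deltaRange[2]) with a random sign.
#'
#' @param nGenes number of genes.
#' @param samplesPerGroup samples per group (two equal groups).
#' @param deIdx integer indices of deregulated genes (may be empty).
#' @param deltaRange range the absolute effect size is drawn from.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param modalityId label for the dataset.
#' @param sampleIds optional sample names (length `2 * samplesPerGroup`).
#' @return list with `dataset` (an [OmicsDataset-class]; columns ordered
#'   group 1 then group 2) and `truth` (logical vector).
#' @export
simMicroarray <- function(nGenes, samplesPerGroup, deIdx = integer(),
                          deltaRange = c(0.5, 2), seed = 1L,
                          modalityId = "microarray", sampleIds = NULL) {
  set.seed(as.integer(seed))
  n <- 2L * samplesPerGroup
  if (is.null(sampleIds)) sampleIds <- sprintf("s%03d", seq_len(n))
  m <- matrix(stats::rnorm(nGenes * n), nGenes, n,
              dimnames = list(sprintf("gene%05d", seq_len(nGenes)), sampleIds))
  truth <- logical(nGenes); truth[deIdx] <- TRUE
  if (length(deIdx)) {
    delta <- stats::runif(length(deIdx), deltaRange[1L], deltaRange[2L]) *
             sample(c(-1, 1), length(deIdx), replace = TRUE)
    g2 <- (samplesPerGroup + 1L):n
    m[deIdx, g2] <- m[deIdx, g2] + delta
  }
  list(dataset = OmicsDataset(m, "continuous", modalityId), truth = truth)
}

#' Simulate an RNA-seq-like negative-binomial count dataset
#'
#' Gene baseline means are drawn log-normally (meanlog 5, sdlog 1.5) and
#' gene dispersions uniformly in `dispRange`; counts are negative binomial
#' with those parameters (equal library size expectation across samples).
#' Deregulated genes have their group-2 mean multiplied by a fold change
#' drawn log-uniformly from `[1/fcMax, 1/fcMin] U [fcMin, fcMax]`.
#'
#' @param nGenes,samplesPerGroup,deIdx,seed,modalityId,sampleIds as in
#'   [simMicroarray()].
#' @param meanlog,sdlog log-normal parameters of the baseline means.
#' @param dispRange range of the NB dispersion (variance = mu + disp*mu^2).
#' @param fcMin,fcMax fold-change band for deregulated genes.
#' @return list with `dataset` (`kind = "counts"`) and `truth`.
#' @export
simRnaseq <- function(nGenes, samplesPerGroup, deIdx = integer(),
                      meanlog = 5, sdlog = 1.5, dispRange = c(0.05, 0.5),
                      fcMin = 1.5, fcMax = 3, seed = 1L,
                      modalityId = "rnaseq", sampleIds = NULL) {
  set.seed(as.integer(seed))
  n <- 2L * samplesPerGroup
  if (is.null(sampleIds)) sampleIds <- sprintf("s%03d", seq_len(n))
  mu <- stats::rlnorm(nGenes, meanlog, sdlog)
  disp <- stats::runif(nGenes, dispRange[1L], dispRange[2L])
  truth <- logical(nGenes); truth[deIdx] <- TRUE
  fc <- rep(1, nGenes)
  if (length(deIdx)) {
    lfc <- stats::runif(length(deIdx), log(fcMin), log(fcMax)) *
           sample(c(-1, 1), length(deIdx), replace = TRUE)
    fc[deIdx] <- exp(lfc)
  }
  muMat <- cbind(matrix(mu, nGenes, samplesPerGroup),
                 matrix(mu * fc, nGenes, samplesPerGroup))
  m <- matrix(stats::rnbinom(nGenes * n, mu = muMat, size = 1 / disp),
              nGenes, n,
              dimnames = list(sprintf("gene%05d", seq_len(nGenes)), sampleIds))
  list(dataset = OmicsDataset(m, "counts", modalityId), truth = truth)
}

#' Simulate a SNP genotype dataset
#'
#' Genotypes are sampled from {0, 1, 2}. Non-deregulated SNPs are uniform
#' over the three genotypes in both groups; deregulated SNPs keep
#' probabilities (1/3, 1/3, 1/3) in group 1 but shift mass from the 0 to
#' the 2 genotype in group 2: `(1/3 - epsilon, 1/3, 1/3 + epsilon)`.
#'
#' @param nGenes,samplesPerGroup,deIdx,seed,modalityId,sampleIds as in
#'   [simMicroarray()].
#' @param epsilon genotype-frequency shift for deregulated SNPs; must not
#'   exceed 1/3.
#' @return list with `dataset` (`kind = "genotype"`) and `truth`.
#' @export
simSnp <- function(nGenes, samplesPerGroup, deIdx = integer(),
                   epsilon = 0.25, seed = 1L, modalityId = "snp",
                   sampleIds = NULL) {
  if (epsilon > 1 / 3) stop("epsilon must not exceed 1/3")
  set.seed(as.integer(seed))
  n <- 2L * samplesPerGroup
  if (is.null(sampleIds)) sampleIds <- sprintf("s%03d", seq_len(n))
  m <- matrix(sample(0:2, nGenes * n, replace = TRUE), nGenes, n,
              dimnames = list(sprintf("gene%05d", seq_len(nGenes)), sampleIds))
  truth <- logical(nGenes); truth[deIdx] <- TRUE
  if (length(deIdx)) {
    g2 <- (samplesPerGroup + 1L):n
    m[deIdx, g2] <- matrix(
      sample(0:2, length(deIdx) * samplesPerGroup, replace = TRUE,
             prob = c(1 / 3 - epsilon, 1 / 3, 1 / 3 + epsilon)),
      length(deIdx), samplesPerGroup)
  }
  list(dataset = OmicsDataset(m, "genotype", modalityId), truth = truth)
}

#' Simulate a uniform reference dataset
#'
#' Non-deregulated genes are Uniform(0,1) in both groups; deregulated
#' genes are shifted upwards by `delta` in group 2 (analysed with the
#' one-sided Wilcoxon rank-sum test by default).
#'
#' @param nGenes,samplesPerGroup,deIdx,seed,modalityId,sampleIds as in
#'   [simMicroarray()].
#' @param delta location shift of deregulated genes in group 2.
#' @return list with `dataset` (`kind = "uniform_like"`) and `truth`.
#' @export
simUniform <- function(nGenes, samplesPerGroup, deIdx = integer(),
                       delta = 0.3, seed = 1L, modalityId = "uniform",
                       sampleIds = NULL) {
  set.seed(as.integer(seed))
  n <- 2L * samplesPerGroup
  if (is.null(sampleIds)) sampleIds <- sprintf("s%03d", seq_len(n))
  m <- matrix(stats::runif(nGenes * n), nGenes, n,
              dimnames = list(sprintf("gene%05d", seq_len(nGenes)), sampleIds))
  truth <- logical(nGenes); truth[deIdx] <- TRUE
  if (length(deIdx)) {
    g2 <- (samplesPerGroup + 1L):n
    m[deIdx, g2] <- m[deIdx, g2] + delta
  }
  list(dataset = OmicsDataset(m, "uniform_like", modalityId), truth = truth)
}

#' Simulate a pair of correlated microarray datasets
#'
#' For every non-deregulated gene the two datasets' rows are
#' `(X, rho * X + sqrt(1 - rho^2) * Z)` with X, Z iid standard normal per
#' sample, so the population Pearson correlation between the paired rows is
#' exactly `rho` (identical rows at `rho = 1`). Deregulated genes represent
#' the same biological signal in both datasets: the additive group-2 shift
#' (drawn as in [simMicroarray()]) is shared, but the noise is independent,
#' so no fixed correlation level is imposed on deregulated rows.
#'
#' @param nGenes,samplesPerGroup,deIdx,deltaRange,seed,sampleIds as in
#'   [simMicroarray()].
#' @param rho target correlation of non-deregulated rows, in `[0, 1]`.
#' @param modalityIds labels for the two datasets.
#' @return list with `datasets` (list of two [OmicsDataset-class]) and
#'   `truth`.
#' @export
simCorrelatedPair <- function(nGenes, samplesPerGroup, rho, deIdx = integer(),
                              deltaRange = c(0.5, 2), seed = 1L,
                              modalityIds = c("micro1", "micro2"),
                              sampleIds = NULL) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  set.seed(as.integer(seed))
  n <- 2L * samplesPerGroup
  if (is.null(sampleIds)) sampleIds <- sprintf("s%03d", seq_len(n))
  gid <- sprintf("gene%05d", seq_len(nGenes))
  X <- matrix(stats::rnorm(nGenes * n), nGenes, n,
              dimnames = list(gid, sampleIds))
  Z <- matrix(stats::rnorm(nGenes * n), nGenes, n,
              dimnames = list(gid, sampleIds))
  Y <- rho * X + sqrt(1 - rho^2) * Z
  truth <- logical(nGenes); truth[deIdx] <- TRUE
  if (length(deIdx)) {
    delta <- stats::runif(length(deIdx), deltaRange[1L], deltaRange[2L]) *
             sample(c(-1, 1), length(deIdx), replace = TRUE)
    g2 <- (samplesPerGroup + 1L):n
    # deregulated rows: shared shift, independent noise in each dataset
    X[deIdx, ] <- stats::rnorm(length(deIdx) * n)
    Y[deIdx, ] <- stats::rnorm(length(deIdx) * n)
    X[deIdx, g2] <- X[deIdx, g2] + delta
    Y[deIdx, g2] <- Y[deIdx, g2] + delta
  }
  list(datasets = list(OmicsDataset(X, "continuous", modalityIds[1L]),
                       OmicsDataset(Y, "continuous", modalityIds[2L])),
       truth = truth)
}

#' Assemble a complete simulation scenario
#'
#' Builds the two benchmark settings with their ground-truth bookkeeping.
#'
#' `"different_modalities"`: four modalities (negative-binomial counts,
#' microarray-like continuous, SNP genotypes, uniform reference) over the
#' same samples. Defaults: 2000 genes, deregulation counts (1600, 1200,
#' 800, 400) for (rnaseq, microarray, snp, uniform), 400 genes deregulated
#' in all modalities, 10 samples per group. After a seeded shuffle of the
#' genes, the first `commonDe` genes are deregulated in every modality and
#' each modality's remaining deregulated genes follow in the shuffled
#' order, so the deregulation sets are nested and the "same behaviour in
#' all modalities" subset is the common block plus the genes deregulated
#' nowhere.
#'
#' `"correlated_modalities"`: two microarray-like datasets with per-gene
#' cross-dataset correlation `rho` among non-deregulated genes. Defaults:
#' 2000 genes, 10 samples per group, 1000 genes deregulated in both
#' datasets (`deCount = commonDe = 1000`), `rho` in `[0, 1]`.
#'
#' @param name `"different_modalities"` or `"correlated_modalities"`.
#' @param nGenes total genes.
#' @param samplesPerGroup samples per group.
#' @param deCounts named or ordered vector of per-modality deregulation
#'   counts (different_modalities).
#' @param commonDe genes deregulated in every modality.
#' @param deCount deregulated genes (correlated_modalities; always common
#'   to both datasets).
#' @param rho cross-dataset correlation (correlated_modalities).
#' @param nModalities use only the first `nModalities` modalities of the
#'   different-modalities setting (2 to 4).
#' @param seed RNG seed.
#' @param ... forwarded effect-size arguments (`deltaRange`, `epsilon`,
#'   `delta`, `fcMin`, `fcMax`, ...).
#' @return a [SimulatedStudy-class].
#' @export
assembleScenario <- function(name = c("different_modalities",
                                      "correlated_modalities"),
                             nGenes = 2000L, samplesPerGroup = 10L,
                             deCounts = c(rnaseq = 1600L, microarray = 1200L,
                                          snp = 800L, uniform = 400L),
                             commonDe = 400L, deCount = 1000L, rho = 0.6,
                             nModalities = 4L, seed = 1L, ...) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop(sprintf("unknown scenario '%s'; valid: %s", name[1L],
                 "different_modalities, correlated_modalities")))
  extras <- list(...)
  arg <- function(key, default) {
    if (key %in% names(extras)) extras[[key]] else default
  }
  n <- 2L * samplesPerGroup
  sid <- sprintf("s%03d", seq_len(n))
  design <- StudyDesign(sid, rep(c("g1", "g2"), each = samplesPerGroup),
                        outcomeType = "dichotomous")
  set.seed(as.integer(seed))
  shuffle <- sample.int(nGenes)

  if (name == "correlated_modalities") {
    deIdx <- shuffle[seq_len(min(deCount, nGenes))]
    pair <- simCorrelatedPair(nGenes, samplesPerGroup, rho = rho,
                              deIdx = deIdx,
                              deltaRange = arg("deltaRange", c(0.5, 2)),
                              seed = as.integer(seed) + 1L, sampleIds = sid)
    truth <- cbind(micro1 = pair$truth, micro2 = pair$truth)
    rownames(truth) <- featureIds(pair$datasets[[1L]])
    return(new("SimulatedStudy", datasets = pair$datasets, design = design,
               truth = truth, scenario = name))
  }

  stopifnot(nModalities >= 2L, nModalities <= length(deCounts))
  deCounts <- deCounts[seq_len(nModalities)]
  if (any(deCounts > nGenes)) stop("deregulation counts cannot exceed nGenes")
  if (commonDe > min(deCounts)) {
    stop("commonDe cannot exceed the smallest per-modality count")
  }
  deSets <- lapply(deCounts, function(k) shuffle[seq_len(k)])
  mods <- names(deCounts)
  datasets <- vector("list", length(mods))
  truth <- matrix(FALSE, nGenes, length(mods),
                  dimnames = list(NULL, mods))
  for (i in seq_along(mods)) {
    subSeed <- as.integer(seed) + i
    sim <- switch(mods[i],
      rnaseq = simRnaseq(nGenes, samplesPerGroup, deIdx = deSets[[i]],
                         fcMin = arg("fcMin", 1.5), fcMax = arg("fcMax", 3),
                         seed = subSeed, sampleIds = sid),
      microarray = simMicroarray(nGenes, samplesPerGroup,
                                 deIdx = deSets[[i]],
                                 deltaRange = arg("deltaRange", c(0.5, 2)),
                                 seed = subSeed, sampleIds = sid),
      snp = simSnp(nGenes, samplesPerGroup, deIdx = deSets[[i]],
                   epsilon = arg("epsilon", 0.25), seed = subSeed,
                   sampleIds = sid),
      uniform = simUniform(nGenes, samplesPerGroup, deIdx = deSets[[i]],
                           delta = arg("delta", 0.3), seed = subSeed,
                           sampleIds = sid),
      stop(sprintf("unknown modality '%s'", mods[i])))
    datasets[[i]] <- sim$dataset
    truth[, i] <- sim$truth
  }
  rownames(truth) <- featureIds(datasets[[1L]])
  new("SimulatedStudy", datasets = datasets, design = design, truth = truth,
      scenario = name)
}

#' Write a simulated study to TSV files
#'
#' One matrix TSV per modality, a design TSV (`sample_id`, `outcome`) and
#' a truth TSV (gene by modality indicator matrix).
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
writeScenario <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (ds in studyDatasets(study)) {
    f <- file.path(dir, paste0(modalityId(ds), ".tsv"))
    writeOmicsMatrix(ds, f)
    files <- c(files, f)
  }
  design <- studyDesign(study)
  f <- file.path(dir, "design.tsv")
  utils::write.table(
    data.frame(sample_id = sampleIds(design),
               outcome = as.character(outcome(design))),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.tsv")
  tr <- groundTruth(study)
  utils::write.table(
    data.frame(gene_id = rownames(tr), tr * 1L, check.names = FALSE),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, f))
}
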