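#' @import methods
NULL

.VALID_KINDS <- c("counts", "continuous", "genotype", "uniform_like")

#' OmicsDataset: one modality's feature-by-sample matrix
#'
#' Container for a single omics data modality. Rows are features (genes,
#' methylation sites, SNPs, proteins, ...), columns are samples. The `kind`
#' slot records the measurement type and drives the choice of the default
#' association statistic: `"counts"` (sequencing read counts, non-negative
#' integers), `"continuous"` (approximately normal values such as microarray
#' intensities or proteomics abundances), `"genotype"` (ordinal 0/1/2 allele
#' dosages) or `"uniform_like"` (generic bounded numeric values analysed
#' rank-based).
#'
#' @slot modalityId single character label identifying the modality.
#' @slot values numeric matrix, features x samples, with unique row and
#'   column names and no missing values.
#' @slot kind one of `"counts"`, `"continuous"`, `"genotype"`,
#'   `"uniform_like"`.
#'
#' @seealso [OmicsDataset()] for the validating constructor,
#'   [readOmicsMatrix()] to load one from a TSV file.
#' @export
setClass("OmicsDataset",
  representation(modalityId = "character", values = "matrix", kind = "character")
)

setValidity("OmicsDataset", function(object) {
  v <- object@values
  msgs <- character()
  if (length(object@modalityId) != 1L || is.na(object@modalityId) ||
      !nzchar(object@modalityId)) {
    msgs <- c(msgs, "modalityId must be a single non-empty string")
  }
  if (length(object@kind) != 1L || !(object@kind %in% .VALID_KINDS)) {
    msgs <- c(msgs, sprintf("kind must be one of: %s",
                            paste(.VALID_KINDS, collapse = ", ")))
  }
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    msgs <- c(msgs, "values must have feature (row) and sample (column) names")
  } else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate feature ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate sample ids")
  }
  if (anyNA(v)) msgs <- c(msgs, "missing values are not supported")
  if (length(msgs) == 0L && is.numeric(v)) {
    if (identical(object@kind, "counts") &&
        (any(v < 0) || any(v != round(v)))) {
      msgs <- c(msgs, "kind='counts' requires non-negative integer values")
    }
    if (identical(object@kind, "genotype") && !all(v %in% c(0, 1, 2))) {
      msgs <- c(msgs, "kind='genotype' requires all values in {0, 1, 2}")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsDataset
#'
#' @param values numeric matrix (features x samples) with row and column names.
#' @param kind measurement type; see [OmicsDataset-class].
#' @param modalityId short label for the modality (defaults to the kind).
#' @return a validated [OmicsDataset-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' ds <- OmicsDataset(m, kind = "counts", modalityId = "rnaseq")
#' featureIds(ds)
#' @export
OmicsDataset <- function(values, kind, modalityId = kind) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("OmicsDataset", modalityId = modalityId, values = values, kind = kind)
}

#' StudyDesign: the sample universe, outcome and covariates
#'
#' Describes the samples involved in a study: the full universe of sample
#' identifiers (the union over all modalities when datasets overlap only
#' partially), the outcome of interest, and optional per-sample covariates.
#' The outcome is typed as `"dichotomous"` (two observed levels, e.g.
#' case/control), `"multiclass"` (three or more levels) or `"continuous"`.
#'
#' @slot sampleIds ordered unique sample identifiers (the universe).
#' @slot outcome per-sample outcome; factor for categorical types, numeric
#'   for continuous.
#' @slot outcomeType one of `"dichotomous"`, `"multiclass"`, `"continuous"`.
#' @slot covariates data.frame of per-sample covariate columns (may have
#'   zero columns).
#' @export
setClass("StudyDesign",
  representation(sampleIds = "character", outcome = "ANY",
                 outcomeType = "character", covariates = "data.frame")
)

setValidity("StudyDesign", function(object) {
  msgs <- character()
  n <- length(object@sampleIds)
  if (n == 0L) msgs <- c(msgs, "empty sample universe")
  if (anyDuplicated(object@sampleIds)) msgs <- c(msgs, "duplicate sample ids")
  if (length(object@outcome) != n) {
    msgs <- c(msgs, "outcome length must equal the number of samples")
  }
  if (anyNA(object@outcome)) msgs <- c(msgs, "missing outcome values")
  ot <- object@outcomeType
  if (length(ot) != 1L || !(ot %in% c("dichotomous", "multiclass", "continuous"))) {
    msgs <- c(msgs, "outcomeType must be dichotomous, multiclass or continuous")
  } else if (ot == "dichotomous") {
    if (length(unique(object@outcome)) != 2L)
      msgs <- c(msgs, "dichotomous outcome must have exactly 2 observed levels")
  } else if (ot == "multiclass") {
    if (length(unique(object@outcome)) < 3L)
      msgs <- c(msgs, "multiclass outcome must have at least 3 observed levels")
  } else if (ot == "continuous" && !is.numeric(object@outcome)) {
    msgs <- c(msgs, "continuous outcome must be numeric")
  }
  if (nrow(object@covariates) != 0L && nrow(object@covariates) != n) {
    msgs <- c(msgs, "covariates must have one row per sample")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StudyDesign
#'
#' @param sampleIds character vector of unique sample identifiers.
#' @param outcome per-sample outcome values; coerced to factor unless
#'   `outcomeType = "continuous"`.
#' @param covariates optional data.frame of per-sample covariates.
#' @param outcomeType `"auto"` (default) detects the type: numeric outcomes
#'   with more distinct values than `maxLevels` are continuous, two observed
#'   levels give a dichotomous design, three or more a multiclass one.
#' @param maxLevels maximum number of distinct numeric values still treated
#'   as categorical under auto-detection.
#' @return a validated [StudyDesign-class] object.
#' @examples
#' design <- StudyDesign(paste0("s", 1:6), rep(c("ctrl", "case"), each = 3))
#' outcomeType(design)
#' @export
StudyDesign <- function(sampleIds, outcome,
                        covariates = data.frame(row.names = sampleIds),
                        outcomeType = c("auto", "dichotomous", "multiclass",
                                        "continuous"),
                        maxLevels = 6L) {
  outcomeType <- match.arg(outcomeType)
  sampleIds <- as.character(sampleIds)
  nlev <- length(unique(outcome))
  if (outcomeType == "auto") {
    outcomeType <- if (is.numeric(outcome) && nlev > maxLevels) "continuous"
                   else if (nlev == 2L) "dichotomous"
                   else if (nlev >= 3L) "multiclass"
                   else stop("degenerate outcome: a single observed level")
  }
  if (nlev < 2L) stop("degenerate outcome: a single observed level")
  if (outcomeType == "continuous") {
    outcome <- as.numeric(outcome)
  } else {
    outcome <- if (is.factor(outcome)) droplevels(outcome) else factor(outcome)
  }
  covariates <- as.data.frame(covariates)
  new("StudyDesign", sampleIds = sampleIds, outcome = outcome,
      outcomeType = outcomeType, covariates = covariates)
}

#' FeatureMapping: linking features across modalities
#'
#' Records which features from different modalities measure the same
#' underlying entity (typically a gene). Each record assigns one
#' (modality, feature) pair to a group; a feature may belong to at most one
#' group. Three strategies resolve groups with several features in one
#' modality: `"one_to_one"` (at most one feature per modality per group,
#' enforced), `"aggregate"` (summarize the member rows with `aggregateFn`
#' before any statistic is computed) and `"expand"` (one output group per
#' cross-modality feature tuple, duplicating rows).
#'
#' @slot table data.frame with columns `group_id`, `modality_id`,
#'   `feature_id`.
#' @slot strategy one of `"one_to_one"`, `"expand"`, `"aggregate"`.
#' @slot aggregateFn `"mean"` or `"median"`; used only when
#'   `strategy = "aggregate"`.
#' @export
setClass("FeatureMapping",
  representation(table = "data.frame", strategy = "character",
                 aggregateFn = "character")
)

setValidity("FeatureMapping", function(object) {
  msgs <- character()
  tb <- object@table
  need <- c("group_id", "modality_id", "feature_id")
  if (!all(need %in% names(tb))) {
    msgs <- c(msgs, sprintf("mapping table must have columns: %s",
                            paste(need, collapse = ", ")))
  } else if (anyDuplicated(tb[, c("modality_id", "feature_id")])) {
    msgs <- c(msgs, "each (modality_id, feature_id) may appear in at most one group")
  }
  if (!(object@strategy %in% c("one_to_one", "expand", "aggregate"))) {
    msgs <- c(msgs, "strategy must be one_to_one, expand or aggregate")
  }
  if (!(object@aggregateFn %in% c("mean", "median"))) {
    msgs <- c(msgs, "aggregateFn must be mean or median")
  }
  if (identical(object@strategy, "one_to_one") && all(need %in% names(tb))) {
    if (anyDuplicated(tb[, c("group_id", "modality_id")]))
      msgs <- c(msgs, "one_to_one mapping: a group has several features in one modality")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureMapping
#'
#' @param table data.frame with columns `group_id`, `modality_id`,
#'   `feature_id` (one row per mapped feature).
#' @param strategy how to resolve many-to-one relations; see
#'   [FeatureMapping-class].
#' @param aggregateFn summary function for `strategy = "aggregate"`.
#' @return a validated [FeatureMapping-class] object.
#' @export
FeatureMapping <- function(table,
                           strategy = c("one_to_one", "expand", "aggregate"),
                           aggregateFn = c("mean", "median")) {
  strategy <- match.arg(strategy)
  aggregateFn <- match.arg(aggregateFn)
  table <- as.data.frame(table)
  for (cl in c("group_id", "modality_id", "feature_id")) {
    if (cl %in% names(table)) table[[cl]] <- as.character(table[[cl]])
  }
  new("FeatureMapping", table = table, strategy = strategy,
      aggregateFn = aggregateFn)
}

#' PermutationPlan: synchronized sample permutations
#'
#' Materializes B random (or exhaustively enumerated) rearrangements of the
#' observed outcome over the sample universe. Row 0 (the first row of the
#' index table) is the identity, i.e. the observed labelling. Every dataset
#' later reads the permuted label of exactly its own samples, so samples
#' shared between modalities receive identical relabelings in every
#' permutation -- the synchronization that preserves between-dataset
#' correlations.
#'
#' @slot B number of permutations (the plan holds B + 1 rows).
#' @slot seed integer seed the plan was built from.
#' @slot labelIdx integer matrix, (B + 1) x n; entry (b, j) is the index of
#'   the sample whose observed outcome is placed at universe position j in
#'   permutation b. Row 1 is `1:n`.
#' @slot sampleIds the sample universe, in plan column order.
#' @slot exhaustive logical; TRUE when all distinct label arrangements were
#'   enumerated instead of sampled.
#' @export
setClass("PermutationPlan",
  representation(B = "integer", seed = "integer", labelIdx = "matrix",
                 sampleIds = "character", exhaustive = "logical")
)

setValidity("PermutationPlan", function(object) {
  msgs <- character()
  n <- length(object@sampleIds)
  if (!identical(dim(object@labelIdx), c(object@B + 1L, n))) {
    msgs <- c(msgs, "labelIdx must be (B + 1) x length(sampleIds)")
  } else {
    if (!identical(object@labelIdx[1L, ], seq_len(n)))
      msgs <- c(msgs, "row 0 of the plan must be the identity (observed labels)")
    bad <- apply(object@labelIdx, 1L, function(r) !identical(sort(r), seq_len(n)))
    if (any(bad))
      msgs <- c(msgs, "every plan row must be a permutation of the samples")
  }
  if (length(msgs)) msgs else TRUE
})

#' NPCResult: global and partial p-values per feature group
#'
#' Result container returned by [runNPC()]. The result table holds, per
#' feature group, the observed partial permutation p-value of each modality,
#' the global p-value under each combining function, and
#' Benjamini-Hochberg-adjusted versions of all of them.
#'
#' @slot table data.frame with columns `group_id`,
#'   `pvalue_partial_<modality>`, `pvalue_global_<combiner>`,
#'   `fdr_partial_<modality>`, `fdr_global_<combiner>`.
#' @slot B number of permutations used.
#' @slot seed seed used for the permutation plan.
#' @slot combiners combining functions applied.
#' @slot modalities modality ids in the order analysed.
#' @slot zeroCorrection whether the zero-avoidance correction was applied.
#' @export
setClass("NPCResult",
  representation(table = "data.frame", B = "integer", seed = "integer",
                 combiners = "character", modalities = "character",
                 zeroCorrection = "logical")
)

setValidity("NPCResult", function(object) {
  msgs <- character()
  tb <- object@table
  if (!("group_id" %in% names(tb))) msgs <- c(msgs, "table must have a group_id column")
  pcols <- grep("^pvalue_", names(tb), value = TRUE)
  if (length(pcols)) {
    pv <- unlist(tb[pcols], use.names = FALSE)
    if (any(pv < 0 | pv > 1)) msgs <- c(msgs, "p-values must lie in [0, 1]")
    if (object@zeroCorrection && length(pv) &&
        min(pv) < 1 / (object@B + 1) - 1e-12)
      msgs <- c(msgs, "zero-corrected p-values must be >= 1/(B+1)")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulatedStudy: datasets plus ground truth
#'
#' Bundle produced by [assembleScenario()]: the simulated datasets, the
#' two-group study design, and the per-gene, per-modality deregulation
#' indicators needed to score methods against the ground truth.
#'
#' @slot datasets list of [OmicsDataset-class] objects.
#' @slot design the [StudyDesign-class] (two equal groups).
#' @slot truth logical matrix, genes x modalities; TRUE where the gene is
#'   deregulated in that modality.
#' @slot scenario scenario name the study was assembled from.
#' @export
setClass("SimulatedStudy",
  representation(datasets = "list", design = "StudyDesign", truth = "matrix",
                 scenario = "character")
)

#' JNCReport: joint-null-criterion diagnostic
#'
#' Output of [doubleKS()]: the first-level Kolmogorov-Smirnov p-values (one
#' per simulated repetition, testing uniformity of the method's per-gene
#' p-values under the complete null) and the second-level KS p-value of
#' those first-level p-values against Uniform(0,1) -- the "dks" p-value. A
#' calibrated method yields a non-significant dks p-value.
#'
#' @slot firstLevel numeric vector of first-level KS p-values.
#' @slot dksP the second-level (double KS) p-value.
#' @slot repetitions number of repetitions performed.
#' @slot scenario `"uncorrelated"` or `"correlated"`.
#' @slot method label of the method evaluated.
#' @export
setClass("JNCReport",
  representation(firstLevel = "numeric", dksP = "numeric",
                 repetitions = "integer", scenario = "character",
                 method = "character")
)

setValidity("JNCReport", function(object) {
  msgs <- character()
  if (length(object@firstLevel) != object@repetitions)
    msgs <- c(msgs, "one first-level p-value per repetition is required")
  if (length(object@firstLevel) &&
      (any(object@firstLevel < 0) || any(object@firstLevel > 1)))
    msgs <- c(msgs, "first-level p-values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
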