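#' @rdname accessors
#' @aliases featureIds,OmicsDataset-method
setMethod("featureIds", "OmicsDataset", function(object) rownames(object@values))

#' @rdname accessors
setMethod("sampleIds", "OmicsDataset", function(object) colnames(object@values))

#' @rdname accessors
setMethod("assayValues", "OmicsDataset", function(object) object@values)

#' @rdname accessors
setMethod("modalityKind", "OmicsDataset", function(object) object@kind)

#' @rdname accessors
setMethod("modalityId", "OmicsDataset", function(object) object@modalityId)

setMethod("show", "OmicsDataset", function(object) {
  cat(sprintf("OmicsDataset '%s' (kind: %s)\n", object@modalityId, object@kind))
  cat(sprintf("  %d features x %d samples\n",
              nrow(object@values), ncol(object@values)))
})

#' @rdname accessors
setMethod("sampleIds", "StudyDesign", function(object) object@sampleIds)

#' @rdname accessors
setMethod("outcome", "StudyDesign", function(object) {
  stats::setNames(object@outcome, object@sampleIds)
})

#' @rdname accessors
setMethod("outcomeType", "StudyDesign", function(object) object@outcomeType)

#' @rdname accessors
setMethod("covariates", "StudyDesign", function(object) object@covariates)

setMethod("show", "StudyDesign", function(object) {
  cat(sprintf("StudyDesign: %d samples, %s outcome", length(object@sampleIds),
              object@outcomeType))
  if (object@outcomeType != "continuous") {
    tb <- table(object@outcome)
    cat(sprintf(" (%s)", paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  cat(sprintf("\n  covariates: %s\n",
              if (ncol(object@covariates)) paste(names(object@covariates),
                                                 collapse = ", ") else "none"))
})

#' @rdname accessors
setMethod("sampleIds", "PermutationPlan", function(object) object@sampleIds)

#' @rdname accessors
setMethod("numPermutations", "PermutationPlan", function(object) object@B)

setMethod("show", "PermutationPlan", function(object) {
  cat(sprintf("PermutationPlan: B = %d over %d samples (seed %d%s)\n",
              object@B, length(object@sampleIds), object@seed,
              if (object@exhaustive) ", exhaustive" else ""))
})

setMethod("permutedLabels", "PermutationPlan",
  function(plan, outcome, b, samples = NULL) {
    stopifnot(b >= 0, b <= plan@B,
              length(outcome) == length(plan@sampleIds))
    lab <- outcome[plan@labelIdx[b + 1L, ]]
    names(lab) <- plan@sampleIds
    if (!is.null(samples)) lab <- lab[samples]
    lab
  })

#' @rdname accessors
setMethod("resultTable", "NPCResult", function(object) object@table)

#' @rdname accessors
setMethod("numPermutations", "NPCResult", function(object) object@B)

setMethod("show", "NPCResult", function(object) {
  cat(sprintf("NPCResult: %d feature groups, %d modalities (%s)\n",
              nrow(object@table), length(object@modalities),
              paste(object@modalities, collapse = ", ")))
  cat(sprintf("  B = %d, seed = %d, combiners: %s, zero correction: %s\n",
              object@B, object@seed, paste(object@combiners, collapse = ", "),
              if (object@zeroCorrection) "on" else "off"))
  gcols <- grep("^pvalue_global_", names(object@table), value = TRUE)
  if (length(gcols)) {
    sig <- vapply(gcols, function(cl) sum(object@table[[cl]] <= 0.05), 0L)
    cat(sprintf("  features with global p <= 0.05: %s\n",
                paste(sprintf("%s=%d", sub("pvalue_global_", "", gcols), sig),
                      collapse = ", ")))
  }
})

#' @rdname accessors
setMethod("groundTruth", "SimulatedStudy", function(object) object@truth)

#' @rdname accessors
setMethod("studyDatasets", "SimulatedStudy", function(object) object@datasets)

#' @rdname accessors
setMethod("studyDesign", "SimulatedStudy", function(object) object@design)

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy '%s': %d modalities, %d genes, %d samples\n",
              object@scenario, length(object@datasets), nrow(object@truth),
              length(object@design@sampleIds)))
  cat(sprintf("  deregulated per modality: %s; in all: %d\n",
              paste(colSums(object@truth), collapse = ", "),
              sum(rowSums(object@truth) == ncol(object@truth))))
})

#' @rdname accessors
setMethod("firstLevelP", "JNCReport", function(object) object@firstLevel)

#' @rdname accessors
setMethod("dksPValue", "JNCReport", function(object) object@dksP)

setMethod("show", "JNCReport", function(object) {
  cat(sprintf("JNCReport for '%s' (%s scenario): %d repetitions\n",
              object@method, object@scenario, object@repetitions))
  cat(sprintf("  double-KS p-value: %.4g\n", object@dksP))
})
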