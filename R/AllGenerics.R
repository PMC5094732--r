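#' Accessors for npcombine classes
#'
#' Small accessor generics exposing the slots of the core data classes
#' without touching `@` directly.
#'
#' @param object an npcombine object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("assayValues", function(object) standardGeneric("assayValues"))

#' @rdname accessors
#' @export
setGeneric("modalityKind", function(object) standardGeneric("modalityKind"))

#' @rdname accessors
#' @export
setGeneric("modalityId", function(object) standardGeneric("modalityId"))

#' @rdname accessors
#' @export
setGeneric("outcome", function(object) standardGeneric("outcome"))

#' @rdname accessors
#' @export
setGeneric("outcomeType", function(object) standardGeneric("outcomeType"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("numPermutations", function(object) standardGeneric("numPermutations"))

#' Outcome labels for one permutation
#'
#' Returns the outcome vector as rearranged by permutation `b` of a
#' [PermutationPlan-class], optionally restricted to a subset of samples.
#' `b = 0` is the observed labelling.
#'
#' @param plan a [PermutationPlan-class].
#' @param outcome the observed outcome vector over the plan's universe.
#' @param b permutation index in `0:B`.
#' @param samples optional character vector of sample ids to restrict to.
#' @return the permuted outcome, named by sample id.
#' @export
setGeneric("permutedLabels",
           function(plan, outcome, b, samples = NULL)
             standardGeneric("permutedLabels"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("studyDatasets", function(object) standardGeneric("studyDatasets"))

#' @rdname accessors
#' @export
setGeneric("studyDesign", function(object) standardGeneric("studyDesign"))

#' @rdname accessors
#' @export
setGeneric("firstLevelP", function(object) standardGeneric("firstLevelP"))

#' @rdname accessors
#' @export
setGeneric("dksPValue", function(object) standardGeneric("dksPValue"))
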