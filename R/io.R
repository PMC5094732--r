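#' Read a feature-by-sample matrix from a TSV file
#'
#' Expects tab-separated text with a header row of sample ids and a first
#' column of feature ids. Values must be fully numeric; for
#' `kind = "counts"` they must additionally be non-negative integers, and
#' for `kind = "genotype"` they must lie in {0, 1, 2}.
#'
#' @param path path to the TSV file.
#' @param kind measurement type of the modality; see [OmicsDataset-class].
#' @param modalityId label for the modality; defaults to the file base name
#'   without extension.
#' @return an [OmicsDataset-class].
#' @export
readOmicsMatrix <- function(path, kind, modalityId = NULL) {
  if (is.null(modalityId)) {
    modalityId <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("format error: expected feature id column plus samples")
  fid <- raw[[1L]]
  if (anyDuplicated(fid)) {
    stop(sprintf("format error in '%s': duplicate feature ids (e.g. '%s')",
                 path, fid[duplicated(fid)][1L]))
  }
  sid <- colnames(raw)[-1L]
  if (anyDuplicated(sid)) {
    stop(sprintf("format error in '%s': duplicate sample ids", path))
  }
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  num <- matrix(num, nrow = nrow(raw), dimnames = list(fid, sid))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "format error in '%s': non-numeric value at feature '%s', sample '%s'",
      path, fid[bad[1L]], sid[bad[2L]]))
  }
  if (identical(kind, "counts")) {
    if (any(num < 0)) stop(sprintf("validation error in '%s': negative counts", path))
    if (any(num != round(num))) {
      bad <- which(num != round(num), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "validation error in '%s': non-integer count %g at feature '%s', sample '%s'",
        path, num[bad[1L], bad[2L]], fid[bad[1L]], sid[bad[2L]]))
    }
  }
  OmicsDataset(num, kind = kind, modalityId = modalityId)
}

#' Write a feature-by-sample matrix to a TSV file
#'
#' Inverse of [readOmicsMatrix()]; values are written with 12 significant
#' digits so a write/read round trip preserves them to that precision.
#'
#' @param dataset an [OmicsDataset-class] (or a plain named matrix).
#' @param path output path.
#' @param idColumn header for the feature id column.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(dataset, path, idColumn = "feature_id") {
  m <- if (is(dataset, "OmicsDataset")) assayValues(dataset) else dataset
  df <- data.frame(rownames(m), signif(m, 12L), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study design table from a TSV file
#'
#' The table must contain a sample id column (first column by default), the
#' outcome column, and any covariate columns. The outcome type is
#' auto-detected (two levels: dichotomous; three or more: multiclass; many
#' distinct numeric values: continuous) unless overridden.
#'
#' @param path path to the TSV file.
#' @param outcomeCol name of the outcome column.
#' @param covariateCols character vector of covariate column names (may be
#'   empty).
#' @param sampleCol name of the sample id column; defaults to the first
#'   column.
#' @param outcomeType override for the detected outcome type.
#' @return a [StudyDesign-class].
#' @export
readStudyDesign <- function(path, outcomeCol, covariateCols = character(),
                            sampleCol = NULL,
                            outcomeType = c("auto", "dichotomous",
                                            "multiclass", "continuous")) {
  outcomeType <- match.arg(outcomeType)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(sampleCol)) sampleCol <- colnames(df)[1L]
  for (cl in c(sampleCol, outcomeCol, covariateCols)) {
    if (!(cl %in% colnames(df)))
      stop(sprintf("column '%s' not found in '%s'", cl, path))
  }
  sid <- as.character(df[[sampleCol]])
  if (anyDuplicated(sid)) {
    dup <- unique(sid[duplicated(sid)])
    sub <- df[sid %in% dup, c(sampleCol, outcomeCol)]
    if (nrow(unique(sub)) != length(dup)) {
      stop(sprintf(
        "inconsistent design in '%s': sample(s) %s repeated with different outcomes",
        path, paste(dup, collapse = ", ")))
    }
    keep <- !duplicated(sid)
    df <- df[keep, , drop = FALSE]
    sid <- sid[keep]
  }
  cov <- df[, covariateCols, drop = FALSE]
  rownames(cov) <- sid
  StudyDesign(sid, df[[outcomeCol]], covariates = cov,
              outcomeType = outcomeType)
}

#' Read a feature mapping table from a TSV file
#'
#' @param path TSV with columns `group_id`, `modality_id`, `feature_id`.
#' @param strategy,aggregateFn see [FeatureMapping()].
#' @return a [FeatureMapping-class].
#' @export
readFeatureMapping <- function(path,
                               strategy = c("one_to_one", "expand", "aggregate"),
                               aggregateFn = c("mean", "median")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  FeatureMapping(df, strategy = match.arg(strategy),
                 aggregateFn = match.arg(aggregateFn))
}

#' Write an NPC result table to a TSV file
#'
#' One row per feature group with the partial, global and FDR-adjusted
#' p-value columns. Values carry 12 significant digits.
#'
#' @param result an [NPCResult-class] (or plain data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNPCResult <- function(result, path) {
  tb <- if (is(result, "NPCResult")) resultTable(result) else result
  num <- vapply(tb, is.numeric, logical(1L))
  tb[num] <- lapply(tb[num], signif, digits = 12L)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check sample-universe consistency
#'
#' Asserts that every dataset's samples are contained in the design's
#' sample universe, and reports samples of the universe not covered by any
#' dataset.
#'
#' @param datasets list of [OmicsDataset-class] objects.
#' @param design a [StudyDesign-class].
#' @return invisibly, the character vector of universe samples used by at
#'   least one dataset.
#' @export
checkSampleUniverse <- function(datasets, design) {
  universe <- sampleIds(design)
  used <- character()
  for (ds in datasets) {
    extra <- setdiff(sampleIds(ds), universe)
    if (length(extra)) {
      stop(sprintf("dataset '%s' has samples outside the design universe: %s",
                   modalityId(ds), paste(utils::head(extra, 5L), collapse = ", ")))
    }
    used <- union(used, sampleIds(ds))
  }
  invisible(universe[universe %in% used])
}
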