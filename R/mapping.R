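#' Re-index datasets onto cross-modality feature groups
#'
#' Applies a [FeatureMapping-class] to a list of datasets so that all
#' modalities become indexed by a shared `group_id`. Aggregation (mean or
#' median over a group's member rows) operates on the raw data values,
#' before any statistic is computed. With `strategy = "expand"` one output
#' group is created per cross-modality feature tuple, duplicating rows as
#' needed; with `strategy = "one_to_one"` rows are simply renamed. Features
#' absent from the mapping are dropped (with a message reporting the count)
#' unless `keepUnmapped = TRUE`, in which case each becomes its own
#' singleton group. Groups with no features in any modality are dropped with
#' a warning. Output group order is deterministic (sorted by group id).
#'
#' @param datasets list of [OmicsDataset-class] objects.
#' @param mapping a [FeatureMapping-class].
#' @param keepUnmapped treat unmapped features as singleton groups instead
#'   of dropping them.
#' @return list of re-indexed [OmicsDataset-class] objects, same order and
#'   modality ids as the input.
#' @examples
#' m1 <- matrix(1:4, 2, 2, dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' map <- FeatureMapping(
#'   data.frame(group_id = "geneA", modality_id = "meth",
#'              feature_id = c("cg1", "cg2")),
#'   strategy = "aggregate", aggregateFn = "mean")
#' ds <- OmicsDataset(m1, "continuous", "meth")
#' applyMapping(list(ds), map)[[1]]
#' @export
applyMapping <- function(datasets, mapping, keepUnmapped = FALSE) {
  stopifnot(is(mapping, "FeatureMapping"))
  tb <- mapping@table
  mids <- vapply(datasets, modalityId, character(1L))
  if (anyDuplicated(mids)) stop("duplicate modality ids across datasets")

  # restrict mapping to features actually present; report unmapped features
  perMod <- stats::setNames(vector("list", length(datasets)), mids)
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    sub <- tb[tb$modality_id == mids[k] & tb$feature_id %in% featureIds(ds), ,
              drop = FALSE]
    unmapped <- setdiff(featureIds(ds), sub$feature_id)
    if (length(unmapped)) {
      if (keepUnmapped) {
        sub <- rbind(sub, data.frame(group_id = unmapped,
                                     modality_id = mids[k],
                                     feature_id = unmapped))
      } else {
        message(sprintf("applyMapping: dropping %d unmapped feature(s) from '%s'",
                        length(unmapped), mids[k]))
      }
    }
    perMod[[k]] <- sub
  }
  allGroups <- sort(unique(unlist(lapply(perMod, `[[`, "group_id"))))
  empty <- setdiff(sort(unique(tb$group_id)), allGroups)
  if (length(empty)) {
    warning(sprintf("applyMapping: %d group(s) with no features in any modality dropped",
                    length(empty)))
  }
  if (!length(allGroups)) stop("no feature groups remain after mapping")

  strategy <- mapping@strategy
  if (strategy == "expand") {
    return(.mappingExpand(datasets, perMod, allGroups))
  }

  aggFun <- match.fun(mapping@aggregateFn)
  out <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    sub <- perMod[[k]]
    groups <- sort(unique(sub$group_id))
    if (!length(groups)) { out[[k]] <- NULL; next }
    vals <- assayValues(ds)
    if (strategy == "one_to_one") {
      if (anyDuplicated(sub$group_id))
        stop(sprintf("one_to_one mapping violated for modality '%s'", mids[k]))
      m <- vals[sub$feature_id, , drop = FALSE]
      rownames(m) <- sub$group_id
      m <- m[order(rownames(m)), , drop = FALSE]
    } else { # aggregate
      rows <- lapply(groups, function(g) {
        fm <- vals[sub$feature_id[sub$group_id == g], , drop = FALSE]
        apply(fm, 2L, aggFun)
      })
      m <- do.call(rbind, rows)
      rownames(m) <- groups
    }
    kind <- modalityKind(ds)
    # aggregated counts are generally no longer integers
    if (kind %in% c("counts", "genotype") && any(m != round(m))) kind <- "continuous"
    out[[k]] <- OmicsDataset(m, kind = kind, modalityId = mids[k])
  }
  out[!vapply(out, is.null, logical(1L))]
}

# expand strategy: one output group per cross-modality feature tuple
.mappingExpand <- function(datasets, perMod, allGroups) {
  mids <- names(perMod)
  tuples <- lapply(allGroups, function(g) {
    feats <- lapply(perMod, function(sub) sub$feature_id[sub$group_id == g])
    feats <- feats[vapply(feats, length, 0L) > 0L]
    grid <- expand.grid(feats, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    tid <- if (nrow(grid) > 1L) paste0(g, "|", seq_len(nrow(grid))) else g
    cbind(tuple_id = tid, group_id = g, grid, stringsAsFactors = FALSE)
  })
  out <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    vals <- assayValues(ds)
    pieces <- lapply(tuples, function(tt) {
      if (!(mids[k] %in% colnames(tt))) return(NULL)
      m <- vals[tt[[mids[k]]], , drop = FALSE]
      rownames(m) <- tt$tuple_id
      m
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
    if (!length(pieces)) { out[[k]] <- NULL; next }
    m <- do.call(rbind, pieces)
    m <- m[order(rownames(m)), , drop = FALSE]
    out[[k]] <- OmicsDataset(m, kind = modalityKind(ds), modalityId = mids[k])
  }
  out[!vapply(out, is.null, logical(1L))]
}
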