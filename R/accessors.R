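## Accessors and show methods.

#' @name accessors
#' @title Accessors for mlfas objects
#' @description Slot accessors; user code should prefer these over `@`.
#' @param x an mlfas object.
#' @return `proteinId`, `proteinLength`: the protein's id and length.
#'   `featureTable`: data.frame of feature instances. `featureRanges`: the
#'   instances as an [IRanges::IRanges] with metadata columns.
#'   `layerIds`, `typeIds`: the annotated layers / feature types.
#'   `featureCounts`: named integer abundance vector.
#'   `msValue`, `psValue`, `fasValue`: the scores. `scoreWeights`: the weight
#'   vector used. `scoreFlags`: flags. `resolvedReference`,
#'   `resolvedTarget`: the scored realizations. `scoreResult`: the
#'   [ScoreResult-class] inside a [SearchOutcome-class].
#'   `combinationsEvaluated`: number of path combinations scored.
#'   `searchMode`: the search/baseline mode label.
NULL

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setMethod("proteinId", "ProteinArchitecture", function(x) x@proteinId)

#' @rdname accessors
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
#' @rdname accessors
#' @export
setMethod("proteinLength", "ProteinArchitecture", function(x) x@proteinLength)

#' @rdname accessors
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setMethod("featureTable", "ProteinArchitecture", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("featureRanges", function(x) standardGeneric("featureRanges"))
#' @rdname accessors
#' @export
setMethod("featureRanges", "ProteinArchitecture", function(x) {
  df <- x@features
  ir <- IRanges(start = df$start, end = df$end)
  mcols(ir) <- df[, c("layerId", "typeId", "evalue"), drop = FALSE]
  ir
})

#' @rdname accessors
#' @export
setGeneric("layerIds", function(x) standardGeneric("layerIds"))
#' @rdname accessors
#' @export
setMethod("layerIds", "ProteinArchitecture",
          function(x) sort(unique(x@features$layerId)))

#' @rdname accessors
#' @export
setGeneric("typeIds", function(x) standardGeneric("typeIds"))
#' @rdname accessors
#' @export
setMethod("typeIds", "ProteinArchitecture",
          function(x) sort(unique(x@features$typeId)))

#' @rdname accessors
#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))
#' @rdname accessors
#' @export
setMethod("featureCounts", "FeatureCounts", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("graphInstances", function(x) standardGeneric("graphInstances"))
#' @rdname accessors
#' @export
setMethod("graphInstances", "LayerGraph", function(x) x@instances)

#' @rdname accessors
#' @export
setGeneric("incompatibilityMatrix",
           function(x) standardGeneric("incompatibilityMatrix"))
#' @rdname accessors
#' @export
setMethod("incompatibilityMatrix", "LayerGraph", function(x) x@incompat)

#' @rdname accessors
#' @export
setGeneric("msValue", function(x) standardGeneric("msValue"))
#' @rdname accessors
#' @export
setMethod("msValue", "ScoreResult", function(x) x@ms)
#' @rdname accessors
#' @export
setMethod("msValue", "SearchOutcome", function(x) x@result@ms)

#' @rdname accessors
#' @export
setGeneric("psValue", function(x) standardGeneric("psValue"))
#' @rdname accessors
#' @export
setMethod("psValue", "ScoreResult", function(x) x@ps)
#' @rdname accessors
#' @export
setMethod("psValue", "SearchOutcome", function(x) x@result@ps)

#' @rdname accessors
#' @export
setGeneric("fasValue", function(x) standardGeneric("fasValue"))
#' @rdname accessors
#' @export
setMethod("fasValue", "ScoreResult", function(x) x@fas)
#' @rdname accessors
#' @export
setMethod("fasValue", "SearchOutcome", function(x) x@result@fas)

#' @rdname accessors
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))
#' @rdname accessors
#' @export
setMethod("scoreWeights", "ScoreResult", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("scoreFlags", function(x) standardGeneric("scoreFlags"))
#' @rdname accessors
#' @export
setMethod("scoreFlags", "ScoreResult", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("resolvedReference", function(x) standardGeneric("resolvedReference"))
#' @rdname accessors
#' @export
setMethod("resolvedReference", "ScoreResult", function(x) x@refPath)

#' @rdname accessors
#' @export
setGeneric("resolvedTarget", function(x) standardGeneric("resolvedTarget"))
#' @rdname accessors
#' @export
setMethod("resolvedTarget", "ScoreResult", function(x) x@tgtPath)

#' @rdname accessors
#' @export
setGeneric("scoreResult", function(x) standardGeneric("scoreResult"))
#' @rdname accessors
#' @export
setMethod("scoreResult", "SearchOutcome", function(x) x@result)

#' @rdname accessors
#' @export
setGeneric("combinationsEvaluated",
           function(x) standardGeneric("combinationsEvaluated"))
#' @rdname accessors
#' @export
setMethod("combinationsEvaluated", "SearchOutcome",
          function(x) x@combinationsEvaluated)

#' @rdname accessors
#' @export
setGeneric("searchMode", function(x) standardGeneric("searchMode"))
#' @rdname accessors
#' @export
setMethod("searchMode", "ScoreResult", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("searchMode", "SearchOutcome", function(x) x@mode)

# compact textual form "layer/type:start-end;..." used in TSV output
.architectureString <- function(arch) {
  df <- arch@features
  if (nrow(df) == 0L) return("")
  paste(sprintf("%s/%s:%d-%d", df$layerId, df$typeId, df$start, df$end),
        collapse = ";")
}

setMethod("show", "ProteinArchitecture", function(object) {
  df <- object@features
  cat(sprintf("%s \"%s\" (%d aa): %d instance(s), %d type(s), %d layer(s)\n",
              class(object), object@proteinId, object@proteinLength,
              nrow(df), length(unique(df$typeId)),
              length(unique(df$layerId))))
  if (nrow(df)) print(utils::head(df, 8L))
  if (nrow(df) > 8L) cat("...", nrow(df) - 8L, "more\n")
})

setMethod("show", "FeatureCounts", function(object) {
  cat(sprintf("FeatureCounts: %d feature type(s), %d instance(s) total\n",
              length(object@counts), sum(object@counts)))
})

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf(paste0("ScoringParams: alpha=%.2f maxOverlap=%d weighting=%s ",
                     "priorityThreshold=%d mergePfamSmart=%s\n"),
              object@alpha, object@maxOverlap, object@weighting,
              object@priorityThreshold, object@mergePfamSmart))
  if (length(object@minWeights))
    cat("  minWeights:", paste(names(object@minWeights),
                               object@minWeights, sep = "=", collapse = " "), "\n")
})

setMethod("show", "LayerGraph", function(object) {
  cat(sprintf("LayerGraph \"%s\": %d instance(s), %d incompatible pair(s), maxOverlap=%d\n",
              object@layerId, nrow(object@instances),
              sum(object@incompat) / 2L, object@maxOverlap))
})

setMethod("show", "ScoreResult", function(object) {
  cat(sprintf("ScoreResult %s -> %s [%s]\n  MS=%.4f PS=%.4f FAS=%.4f (alpha=%.2f)\n",
              object@referenceId, object@targetId, object@mode,
              object@ms, object@ps, object@fas, object@alpha))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "SearchOutcome", function(object) {
  cat(sprintf("SearchOutcome [%s], %g combination(s) evaluated\n",
              object@mode, object@combinationsEvaluated))
  show(object@result)
})

#' @rdname accessors
#' @param row.names,optional,... passed on from the generic.
#' @export
as.data.frame.ScoreResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(ref_id = x@referenceId, tgt_id = x@targetId,
             MS = x@ms, PS = x@ps, FAS = x@fas, mode = x@mode,
             stringsAsFactors = FALSE)
}
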