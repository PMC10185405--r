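## Central S4 containers. Feature instances are rows of a features
## data.frame (layerId, typeId, start, end, evalue); coordinates are 1-based
## residue positions, inclusive at both ends (Pfam/InterProScan convention).

.featureCols <- c("layerId", "typeId", "start", "end", "evalue")

emptyFeatureTable <- function() {
  data.frame(layerId = character(0), typeId = character(0),
             start = integer(0), end = integer(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

# canonical instance order: layer, then start, end, type
.canonicalFeatures <- function(df) {
  df <- df[order(df$layerId, df$start, df$end, df$typeId), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.normalizeFeatures <- function(features) {
  if (is.null(features) || nrow(features) == 0L) return(emptyFeatureTable())
  if (!all(c("layerId", "typeId", "start", "end") %in% names(features)))
    stop("features must have columns layerId, typeId, start, end")
  if (is.null(features$evalue)) features$evalue <- NA_real_
  df <- data.frame(layerId = as.character(features$layerId),
                   typeId = as.character(features$typeId),
                   start = as.integer(features$start),
                   end = as.integer(features$end),
                   evalue = as.numeric(features$evalue),
                   stringsAsFactors = FALSE)
  .canonicalFeatures(df)
}

#' ProteinArchitecture: a protein's multi-layered feature annotation
#'
#' Holds the protein identifier, its length in residues, and all annotated
#' feature instances as a data.frame with columns `layerId` (feature class,
#' e.g. `"pfam_smart"`, `"seg"`, `"tmhmm"`), `typeId` (e.g.
#' `"pfam:PF00515"`), `start`, `end` (1-based, inclusive) and `evalue`
#' (`NA` for feature classes without e-values, such as SEG or COILS
#' predictions).
#'
#' @slot proteinId character protein identifier.
#' @slot proteinLength integer protein length in residues.
#' @slot features data.frame of feature instances (see above).
#' @aliases ProteinArchitecture-class
#' @exportClass ProteinArchitecture
setClass("ProteinArchitecture",
         representation(proteinId = "character",
                        proteinLength = "integer",
                        features = "data.frame"))

setValidity("ProteinArchitecture", function(object) {
  msg <- character(0)
  if (length(object@proteinId) != 1L || is.na(object@proteinId) ||
      !nzchar(object@proteinId))
    msg <- c(msg, "proteinId must be a single non-empty string")
  if (length(object@proteinLength) != 1L || is.na(object@proteinLength) ||
      object@proteinLength < 1L)
    msg <- c(msg, "proteinLength must be a positive integer")
  df <- object@features
  if (!identical(names(df), .featureCols)) {
    msg <- c(msg, "features must have columns layerId, typeId, start, end, evalue")
  } else if (nrow(df) > 0L) {
    if (any(is.na(df$layerId) | !nzchar(df$layerId)))
      msg <- c(msg, "layerId entries must be non-empty")
    if (any(is.na(df$typeId) | !nzchar(df$typeId)))
      msg <- c(msg, "typeId entries must be non-empty")
    if (any(is.na(df$start) | is.na(df$end) | df$start < 1L | df$start > df$end))
      msg <- c(msg, "instances need 1 <= start <= end")
    if (length(object@proteinLength) == 1L && !is.na(object@proteinLength) &&
        any(df$end > object@proteinLength, na.rm = TRUE))
      msg <- c(msg, sprintf("instance end exceeds protein length (%d)",
                            object@proteinLength))
    if (any(!is.na(df$evalue) & df$evalue < 0))
      msg <- c(msg, "evalue must be >= 0 when present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinArchitecture
#'
#' @param proteinId protein identifier.
#' @param length protein length in residues (positive integer).
#' @param features data.frame with columns `layerId`, `typeId`, `start`,
#'   `end` and optionally `evalue`. Instances are stored in canonical order
#'   (layer, start, end, type).
#' @return A [ProteinArchitecture-class] object.
#' @examples
#' ProteinArchitecture("p1", 100,
#'   data.frame(layerId = "pfam_smart", typeId = "pfam:PF00515",
#'              start = 10, end = 50, evalue = 1e-8))
#' @export
ProteinArchitecture <- function(proteinId, length, features = emptyFeatureTable()) {
  new("ProteinArchitecture", proteinId = as.character(proteinId),
      proteinLength = as.integer(length),
      features = .normalizeFeatures(features))
}

#' ResolvedArchitecture: one non-redundant realization of an architecture
#'
#' A [ProteinArchitecture-class] whose same-layer instances are one selected
#' path per layer (a maximal set of mutually compatible instances). This is
#' the unit that is scored. Produced by [exhaustiveSearch()],
#' [resolveByEvalue()] or by coercing a `ProteinArchitecture` (which keeps
#' every instance and is only meaningful for the unresolved baseline).
#'
#' @aliases ResolvedArchitecture-class
#' @exportClass ResolvedArchitecture
setClass("ResolvedArchitecture", contains = "ProteinArchitecture")

setAs("ProteinArchitecture", "ResolvedArchitecture", function(from) {
  new("ResolvedArchitecture", proteinId = from@proteinId,
      proteinLength = from@proteinLength, features = from@features)
})

# internal: resolved architecture from selected feature-table rows
.resolveRows <- function(arch, rows) {
  new("ResolvedArchitecture", proteinId = arch@proteinId,
      proteinLength = arch@proteinLength,
      features = .canonicalFeatures(arch@features[rows, , drop = FALSE]))
}

#' FeatureCounts: feature-type abundances in a reference proteome
#'
#' Named positive integer counts, one per feature type; used by the
#' abundance-driven weighting schemes, where rarer types receive larger
#' weights.
#'
#' @slot counts named integer vector, all entries >= 1.
#' @aliases FeatureCounts-class
#' @exportClass FeatureCounts
setClass("FeatureCounts", representation(counts = "integer"))

setValidity("FeatureCounts", function(object) {
  msg <- character(0)
  cnt <- object@counts
  if (length(cnt) == 0L) msg <- c(msg, "counts must be non-empty")
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
    msg <- c(msg, "counts must be named by type_id")
  if (anyDuplicated(names(cnt))) msg <- c(msg, "duplicate type_id in counts")
  if (any(is.na(cnt) | cnt < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param counts named numeric/integer vector of per-type instance counts.
#' @return A [FeatureCounts-class] object.
#' @rdname FeatureCounts-class
#' @export
FeatureCounts <- function(counts) {
  new("FeatureCounts", counts = setNames(as.integer(counts), names(counts)))
}

#' ScoringParams: tunable parameters of the architecture comparison
#'
#' @slot alpha weight of the multiplicity score in the combined score,
#'   in \[0,1\]; default 0.7.
#' @slot maxOverlap residues two same-layer instances may share before they
#'   become mutually exclusive; default 0 (any shared residue creates
#'   redundancy).
#' @slot weighting one of `"auto"` (uniform without a count table, `"ln"`
#'   with one), `"uniform"`, `"ln"`, `"linear"`, `"log10"`, `"root4"`,
#'   `"root8"`.
#' @slot minWeights named numeric vector of ad-hoc per-type minimum weights
#'   in (0,1\]; their sum must stay below 1.
#' @slot priorityThreshold path-combination count above which
#'   [compareArchitectures()] switches from the exhaustive search to the
#'   priority heuristic; default 500.
#' @slot mergePfamSmart merge the `"pfam"` and `"smart"` layers into one
#'   `"pfam_smart"` layer on input (both are pHMM-based and overlap heavily);
#'   default `TRUE`.
#' @aliases ScoringParams-class
#' @exportClass ScoringParams
setClass("ScoringParams",
         representation(alpha = "numeric", maxOverlap = "integer",
                        weighting = "character", minWeights = "numeric",
                        priorityThreshold = "integer",
                        mergePfamSmart = "logical"))

setValidity("ScoringParams", function(object) {
  msg <- character(0)
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (length(object@maxOverlap) != 1L || is.na(object@maxOverlap) ||
      object@maxOverlap < 0L)
    msg <- c(msg, "maxOverlap must be a non-negative integer")
  if (!object@weighting %in% c("auto", "uniform", "ln", "linear", "log10",
                               "root4", "root8"))
    msg <- c(msg, "unknown weighting scheme")
  mw <- object@minWeights
  if (length(mw)) {
    if (is.null(names(mw)) || any(!nzchar(names(mw))))
      msg <- c(msg, "minWeights must be named by type_id")
    if (any(mw <= 0 | mw > 1)) msg <- c(msg, "minWeights must lie in (0, 1]")
    if (sum(mw) >= 1) msg <- c(msg, "sum of minWeights must be < 1")
  }
  if (length(object@priorityThreshold) != 1L || object@priorityThreshold < 1L)
    msg <- c(msg, "priorityThreshold must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @param alpha,maxOverlap,weighting,minWeights,priorityThreshold,mergePfamSmart
#'   see the class slots.
#' @return A [ScoringParams-class] object.
#' @rdname ScoringParams-class
#' @examples
#' ScoringParams()                       # defaults: alpha 0.7, maxOverlap 0
#' ScoringParams(weighting = "ln", minWeights = c("tmhmm:tm" = 0.2))
#' @export
ScoringParams <- function(alpha = 0.7, maxOverlap = 0L, weighting = "auto",
                          minWeights = numeric(0), priorityThreshold = 500L,
                          mergePfamSmart = TRUE) {
  new("ScoringParams", alpha = as.numeric(alpha),
      maxOverlap = as.integer(maxOverlap), weighting = weighting,
      minWeights = minWeights,
      priorityThreshold = as.integer(priorityThreshold),
      mergePfamSmart = isTRUE(mergePfamSmart))
}

#' LayerGraph: per-layer compatibility structure over feature instances
#'
#' Vertices are the layer's feature instances in protein order (start, end,
#' type); two instances are *incompatible* when they share more than
#' `maxOverlap` residues. The maximal sets of pairwise-compatible instances
#' are the alternative non-redundant paths through the layer.
#'
#' @slot layerId the layer.
#' @slot instances data.frame of the layer's instances with column `row`
#'   pointing back into the architecture's feature table.
#' @slot incompat symmetric logical incompatibility matrix.
#' @slot maxOverlap the overlap cut-off used.
#' @aliases LayerGraph-class
#' @exportClass LayerGraph
setClass("LayerGraph",
         representation(layerId = "character", instances = "data.frame",
                        incompat = "matrix", maxOverlap = "integer"))

setValidity("LayerGraph", function(object) {
  n <- nrow(object@instances)
  m <- object@incompat
  if (!is.logical(m) || !identical(dim(m), c(n, n)))
    return("incompat must be an n x n logical matrix")
  if (n > 0L && (!identical(m, t(m)) || any(diag(m))))
    return("incompat must be symmetric with a FALSE diagonal")
  TRUE
})

#' ScoreResult: scores and resolved architectures for one protein pair
#'
#' @slot referenceId,targetId the compared proteins (the score is asymmetric;
#'   weights and type sets come from the reference).
#' @slot ms,ps,fas multiplicity, positional and combined score, each in
#'   \[0,1\], with `fas = alpha * ms + (1 - alpha) * ps`.
#' @slot alpha the mixing parameter used.
#' @slot mode one of `"exhaustive"`, `"priority"`, `"baseline_evalue"`,
#'   `"baseline_unresolved"`.
#' @slot weights named weight vector over the reference path's feature types
#'   (sums to 1; empty for an empty reference).
#' @slot refPath,tgtPath the scored [ResolvedArchitecture-class] objects
#'   (`NULL` for the unresolved baseline).
#' @slot flags character flags, e.g. `"empty-reference"`.
#' @aliases ScoreResult-class
#' @exportClass ScoreResult
setClass("ScoreResult",
         representation(referenceId = "character", targetId = "character",
                        ms = "numeric", ps = "numeric", fas = "numeric",
                        alpha = "numeric", mode = "character",
                        weights = "numeric", refPath = "ANY", tgtPath = "ANY",
                        flags = "character"))

setValidity("ScoreResult", function(object) {
  msg <- character(0)
  eps <- 1e-9
  for (s in c("ms", "ps", "fas")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v < -eps || v > 1 + eps)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  if (abs(object@fas -
          (object@alpha * object@ms + (1 - object@alpha) * object@ps)) > eps)
    msg <- c(msg, "fas must equal alpha * ms + (1 - alpha) * ps")
  if (!object@mode %in% c("exhaustive", "priority", "baseline_evalue",
                          "baseline_unresolved"))
    msg <- c(msg, "unknown mode")
  if (length(msg)) msg else TRUE
})

#' SearchOutcome: result of a score-maximizing search
#'
#' @slot result the [ScoreResult-class] of the best realization pair.
#' @slot combinationsEvaluated number of (reference path, target path)
#'   combinations scored; equals [countPathCombinations()] in exhaustive
#'   mode.
#' @slot mode `"exhaustive"` or `"priority"`.
#' @aliases SearchOutcome-class
#' @exportClass SearchOutcome
setClass("SearchOutcome",
         representation(result = "ScoreResult",
                        combinationsEvaluated = "numeric",
                        mode = "character"))

#' PerturbationSpec: seeded stochastic edit model for synthetic architectures
#'
#' Emulates the architecture changes seen between diverging orthologs:
#' feature-type loss, instance duplication, positional divergence, and
#' redundant decoy annotation.
#'
#' @slot pLoss probability of dropping a feature type entirely.
#' @slot pDup per-instance probability of duplication.
#' @slot shiftSd SD of the positional shift, as a fraction of protein length.
#' @slot pRedundant per-instance probability of adding an overlapping
#'   same-layer decoy instance under a fresh type id.
#' @slot seed RNG seed; perturbation is a pure function of (architecture,
#'   spec).
#' @aliases PerturbationSpec-class
#' @exportClass PerturbationSpec
setClass("PerturbationSpec",
         representation(pLoss = "numeric", pDup = "numeric",
                        shiftSd = "numeric", pRedundant = "numeric",
                        seed = "integer"))

setValidity("PerturbationSpec", function(object) {
  p <- c(object@pLoss, object@pDup, object@pRedundant)
  if (any(is.na(p) | p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  if (is.na(object@shiftSd) || object@shiftSd < 0) return("shiftSd must be >= 0")
  TRUE
})

#' @param pLoss,pDup,shiftSd,pRedundant,seed see the class slots.
#' @return A [PerturbationSpec-class] object.
#' @rdname PerturbationSpec-class
#' @export
PerturbationSpec <- function(pLoss = 0, pDup = 0, shiftSd = 0,
                             pRedundant = 0, seed = 1L) {
  new("PerturbationSpec", pLoss = as.numeric(pLoss), pDup = as.numeric(pDup),
      shiftSd = as.numeric(shiftSd), pRedundant = as.numeric(pRedundant),
      seed = as.integer(seed))
}
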