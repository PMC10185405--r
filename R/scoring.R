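## Feature weighting and the multiplicity / positional / combined scores,
## plus the two baseline scorers (e-value resolution, unresolved).
##
## Weights: uniform w_i = 1/n, or abundance-driven w_i proportional to
## 1/(f(o_i)+1) with f in {ln, identity, log10, x^(1/4), x^(1/8)} and o_i
## the type's instance count in the reference proteome. The textbook form
## carries a numerator sum_l(ln(o_l)+1) that is constant across i and
## cancels under the sum-to-one normalization; it is therefore omitted.

.weightTransforms <- list(
  ln = function(x) log(x),
  linear = function(x) x,
  log10 = function(x) log10(x),
  root4 = function(x) x^0.25,
  root8 = function(x) x^0.125)

#' Compute the feature-type weight vector
#'
#' Weights are computed over the feature types of the reference path and sum
#' to 1. With `weighting = "auto"` (the default) the scheme is uniform
#' without a count table and `"ln"` with one. Types missing from the count
#' table are assumed to have count 1 (the most conservative choice: maximal
#' weight) with a warning. Ad-hoc minimum weights floor the listed types;
#' the remaining mass is distributed over the unfloored types proportionally
#' to their unconstrained weights (iterated, so no floor is violated by the
#' rescaling).
#'
#' @param typeIds non-empty character vector of feature types.
#' @param counts a [FeatureCounts-class] or `NULL`.
#' @param params a [ScoringParams-class] (`weighting`, `minWeights`).
#' @return Named numeric weight vector over `typeIds`, summing to 1.
#' @examples
#' computeWeights(c("a", "b", "c", "d"))                  # uniform, 0.25 each
#' computeWeights(c("a", "b"), FeatureCounts(c(a = 1, b = 100)),
#'                ScoringParams(weighting = "ln"))
#' @export
computeWeights <- function(typeIds, counts = NULL, params = ScoringParams()) {
  typeIds <- unique(as.character(typeIds))
  n <- length(typeIds)
  if (n == 0L) stop("cannot compute weights for an empty type set")
  scheme <- params@weighting
  if (scheme == "auto") scheme <- if (is.null(counts)) "uniform" else "ln"
  if (scheme == "uniform") {
    w <- setNames(rep(1 / n, n), typeIds)
  } else {
    if (is.null(counts))
      stop("abundance-driven weighting (", scheme, ") requires a count table")
    stopifnot(is(counts, "FeatureCounts"))
    o <- featureCounts(counts)[typeIds]
    if (anyNA(o)) {
      missing <- typeIds[is.na(o)]
      warning("type(s) absent from count table, assuming count 1: ",
              paste(missing, collapse = ", "))
      o[is.na(o)] <- 1L
    }
    p <- 1 / (.weightTransforms[[scheme]](as.numeric(o)) + 1)
    w <- setNames(p / sum(p), typeIds)
  }
  .applyMinWeights(w, params@minWeights)
}

# floor listed types at their minimum weight; redistribute the remaining
# mass proportionally to the unconstrained weights, iterating until no
# listed type falls below its floor
.applyMinWeights <- function(w, minWeights) {
  mw <- minWeights[names(minWeights) %in% names(w)]
  if (length(mw) == 0L) return(w)
  if (sum(mw) >= 1)
    stop("sum of applicable minimum weights must be < 1 (got ", sum(mw), ")")
  w0 <- w
  fixed <- character(0)
  repeat {
    free <- setdiff(names(w0), fixed)
    mass <- 1 - sum(mw[fixed])
    w <- w0
    w[fixed] <- mw[fixed]
    if (length(free)) {
      w[free] <- w0[free] / sum(w0[free]) * mass
    } else {
      # every type floored and binding: hand the leftover back pro rata
      w <- mw[names(w0)]
      w <- w + (1 - sum(w)) * w0 / sum(w0)
    }
    viol <- names(mw)[!(names(mw) %in% fixed) &
                        w[names(mw)] < mw - 1e-12]
    if (length(viol) == 0L) break
    fixed <- c(fixed, viol)
  }
  w
}

# per-type instance counts and relative midpoints of a resolved architecture
.typeProfile <- function(resolved) {
  df <- resolved@features
  mids <- (df$start + df$end) / 2 / resolved@proteinLength
  split(mids, df$typeId)
}

.msTerm <- function(nS, nO) if (nO == 0L) 0 else min(nS * nO / nS^2, 1)

.psTerm <- function(midsS, midsO) {
  if (length(midsO) == 0L) return(0)
  s <- vapply(midsS, function(p) 1 - min(abs(p - midsO)), numeric(1L))
  sum(s) / length(midsS)
}

#' Multiplicity score
#'
#' Weighted agreement in feature-type content and copy number:
#' `MS = sum_i w_i * min(N_i^S * N_i^O / (N_i^S)^2, 1)` over the reference's
#' feature types, with an upper bound of 1 per type when the target carries
#' more copies than the reference. Types absent from the target contribute
#' 0.
#'
#' @param ref,tgt [ResolvedArchitecture-class] objects (reference and
#'   target).
#' @param w named weight vector covering the reference's feature types (see
#'   [computeWeights()]).
#' @return MS in \[0, 1\].
#' @export
multiplicityScore <- function(ref, tgt, w) {
  .checkScoreArgs(ref, tgt, w)
  refProf <- .typeProfile(ref)
  tgtProf <- .typeProfile(tgt)
  sum(vapply(names(refProf), function(t) {
    w[[t]] * .msTerm(length(refProf[[t]]),
                     length(tgtProf[[t]]))
  }, numeric(1L)))
}

#' Positional score
#'
#' Weighted agreement of the relative positions of shared feature types.
#' The relative position of an instance is its midpoint `(start + end) / 2`
#' divided by the protein length (exact arithmetic, no rounding). Each
#' reference instance is matched to the target instance of the same type
#' with the closest relative midpoint (many-to-one matching is allowed):
#' `PS = sum_i (w_i / N_i^S) * sum_j (1 - min_l |P_ij^S - P_il^O|)`.
#' Types absent from the target contribute 0.
#'
#' @inheritParams multiplicityScore
#' @return PS in \[0, 1\].
#' @export
positionalScore <- function(ref, tgt, w) {
  .checkScoreArgs(ref, tgt, w)
  refProf <- .typeProfile(ref)
  tgtProf <- .typeProfile(tgt)
  sum(vapply(names(refProf), function(t) {
    mo <- tgtProf[[t]]
    w[[t]] * .psTerm(refProf[[t]], if (is.null(mo)) numeric(0) else mo)
  }, numeric(1L)))
}

.checkScoreArgs <- function(ref, tgt, w) {
  stopifnot(is(ref, "ResolvedArchitecture"), is(tgt, "ResolvedArchitecture"))
  refTypes <- unique(ref@features$typeId)
  if (!all(refTypes %in% names(w)))
    stop("weight vector must cover every feature type of the reference path")
  invisible(NULL)
}

# shared core: scores two resolved architectures and assembles a ScoreResult
.scorePair <- function(ref, tgt, counts, params, mode,
                       keepPaths = TRUE) {
  refTypes <- unique(ref@features$typeId)
  if (length(refTypes) == 0L) {
    return(new("ScoreResult", referenceId = ref@proteinId,
               targetId = tgt@proteinId, ms = 0, ps = 0, fas = 0,
               alpha = params@alpha, mode = mode, weights = numeric(0),
               refPath = if (keepPaths) ref else NULL,
               tgtPath = if (keepPaths) tgt else NULL,
               flags = "empty-reference"))
  }
  w <- computeWeights(refTypes, counts, params)
  ms <- multiplicityScore(ref, tgt, w)
  ps <- positionalScore(ref, tgt, w)
  new("ScoreResult", referenceId = ref@proteinId, targetId = tgt@proteinId,
      ms = ms, ps = ps, fas = params@alpha * ms + (1 - params@alpha) * ps,
      alpha = params@alpha, mode = mode, weights = w,
      refPath = if (keepPaths) ref else NULL,
      tgtPath = if (keepPaths) tgt else NULL,
      flags = character(0))
}

#' Combined architecture similarity score for a resolved pair
#'
#' `FAS = alpha * MS + (1 - alpha) * PS` with weights computed over the
#' feature types of the reference path. The score is asymmetric: it reaches
#' 1 when the reference architecture resembles a (sub-)architecture of the
#' target, and 0 when no feature type is shared. An empty reference scores
#' 0 and is flagged `"empty-reference"` rather than raising an error, so
#' pipelines survive unannotated proteins.
#'
#' @param ref,tgt [ResolvedArchitecture-class] objects; a plain
#'   [ProteinArchitecture-class] is accepted and scored as-is (all
#'   instances).
#' @param counts optional [FeatureCounts-class] for abundance weighting.
#' @param params a [ScoringParams-class].
#' @param mode label recorded in the result (default `"exhaustive"`).
#' @return A [ScoreResult-class].
#' @seealso [compareArchitectures()] for the full search,
#'   [scoreUnresolved()] and [resolveByEvalue()] for the baselines.
#' @export
fasScore <- function(ref, tgt, counts = NULL, params = ScoringParams(),
                     mode = "exhaustive") {
  ref <- as(ref, "ResolvedArchitecture")
  tgt <- as(tgt, "ResolvedArchitecture")
  .scorePair(ref, tgt, counts, params, mode)
}

#' Resolve overlaps by e-value minimization (baseline)
#'
#' The state-of-the-art baseline: per layer, repeatedly keep the remaining
#' instance with the smallest e-value and discard everything incompatible
#' with it. Instances without e-values (SEG/fLPS/COILS/tmhmm classes) rank
#' after all instances with e-values; ties are broken by (start, type) for
#' determinism. The result is a maximal compatible set, i.e. one of the
#' enumerated paths.
#'
#' @param arch a [ProteinArchitecture-class].
#' @param maxOverlap overlap cut-off in residues.
#' @return A [ResolvedArchitecture-class].
#' @export
resolveByEvalue <- function(arch, maxOverlap = 0L) {
  stopifnot(is(arch, "ProteinArchitecture"))
  df <- arch@features
  if (nrow(df) == 0L) return(as(arch, "ResolvedArchitecture"))
  keep <- integer(0)
  for (layer in sort(unique(df$layerId))) {
    g <- buildLayerGraph(arch, layer, maxOverlap)
    sub <- g@instances
    ord <- order(is.na(sub$evalue), sub$evalue, sub$start, sub$typeId)
    sel <- integer(0)
    for (i in ord) {
      if (!any(g@incompat[i, sel])) sel <- c(sel, i)
    }
    keep <- c(keep, sub$row[sel])
  }
  .resolveRows(arch, sort.int(keep))
}

#' Score a protein pair on the unresolved architectures (baseline)
#'
#' MS/PS/FAS computed directly on the complete, possibly overlapping
#' instance sets of both proteins — i.e. each layer's "path" is all of its
#' instances. Redundant agreeing annotations can buffer missing features
#' here, so this baseline can over- or under-estimate the similarity
#' relative to the score-maximizing resolution.
#'
#' @inheritParams fasScore
#' @return A [ScoreResult-class] with mode `"baseline_unresolved"` (no
#'   resolved paths attached).
#' @export
scoreUnresolved <- function(archS, archO, counts = NULL,
                            params = ScoringParams()) {
  .scorePair(as(archS, "ResolvedArchitecture"),
             as(archO, "ResolvedArchitecture"),
             counts, params, "baseline_unresolved", keepPaths = FALSE)
}

#' Score a protein pair after e-value overlap resolution (baseline)
#'
#' Convenience wrapper: both architectures are resolved with
#' [resolveByEvalue()] and the resolved pair is scored with [fasScore()].
#'
#' @inheritParams fasScore
#' @return A [ScoreResult-class] with mode `"baseline_evalue"`.
#' @export
scoreByEvalue <- function(archS, archO, counts = NULL,
                          params = ScoringParams()) {
  fasScore(resolveByEvalue(archS, params@maxOverlap),
           resolveByEvalue(archO, params@maxOverlap),
           counts, params, mode = "baseline_evalue")
}
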