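## Score-maximizing overlap resolution. The exhaustive mode scores every
## combination of assembled reference and target realizations (one path per
## layer on each side) and keeps the maximum — this is necessary, not just
## convenient, because the weight vector is computed over the reference
## path's full type set, which couples the layers: choosing a different path
## in one layer changes every type's weight. The priority mode replaces the
## full cross product with a small candidate set per protein (one greedy
## realization plus one per multi-instance feature type), keeping work
## linear in the number of alternative paths.

# iterate over all assembled realizations (cross product of per-layer
# paths) in lexicographic order; calls fn(rows) with feature-table rows
.forEachAssembly <- function(paths, fn) {
  nl <- length(paths)
  if (nl == 0L) { fn(integer(0)); return(invisible()) }
  counts <- vapply(paths, length, integer(1L))
  idx <- rep(1L, nl)
  repeat {
    rows <- sort.int(unlist(lapply(seq_len(nl), function(i) paths[[i]][[idx[i]]]),
                            use.names = FALSE))
    fn(rows)
    k <- nl
    while (k >= 1L) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= counts[k]) break
      idx[k] <- 1L
      k <- k - 1L
    }
    if (k < 1L) break
  }
  invisible()
}

.allAssemblies <- function(arch, maxOverlap) {
  paths <- .architecturePaths(arch, maxOverlap)
  out <- list()
  .forEachAssembly(paths, function(rows) out[[length(out) + 1L]] <<- rows)
  out
}

# fast internal profile of a candidate realization
.assemblyProfile <- function(arch, rows) {
  df <- arch@features[rows, , drop = FALSE]
  list(types = df$typeId,
       mids = (df$start + df$end) / 2 / arch@proteinLength)
}

# score a (reference, target) profile pair; returns FAS only
.profileFas <- function(refProf, tgtProf, counts, params) {
  refTypes <- unique(refProf$types)
  if (length(refTypes) == 0L) return(0)
  w <- computeWeights(refTypes, counts, params)
  refSplit <- split(refProf$mids, refProf$types)
  tgtSplit <- split(tgtProf$mids, tgtProf$types)
  ms <- ps <- 0
  for (t in names(refSplit)) {
    mS <- refSplit[[t]]
    mO <- tgtSplit[[t]]
    if (is.null(mO)) next
    ms <- ms + w[[t]] * .msTerm(length(mS), length(mO))
    ps <- ps + w[[t]] * .psTerm(mS, mO)
  }
  params@alpha * ms + (1 - params@alpha) * ps
}

#' Exhaustive score-maximizing search
#'
#' Evaluates the FAS score for every combination of assembled alternative
#' paths through the reference and target architectures (all
#' [countPathCombinations()] of them) and returns the best-scoring pair of
#' representative architectures. Ties are broken by the lexicographically
#' first combination, so results are deterministic. The returned FAS is by
#' construction greater than or equal to the score of any single path pair,
#' including the e-value-resolved baseline.
#'
#' @param archS,archO reference and target [ProteinArchitecture-class].
#' @param counts optional [FeatureCounts-class] for abundance weighting.
#' @param params a [ScoringParams-class].
#' @return A [SearchOutcome-class] with mode `"exhaustive"`.
#' @export
exhaustiveSearch <- function(archS, archO, counts = NULL,
                             params = ScoringParams()) {
  refAsm <- .allAssemblies(archS, params@maxOverlap)
  tgtAsm <- .allAssemblies(archO, params@maxOverlap)
  tgtProfs <- lapply(tgtAsm, function(r) .assemblyProfile(archO, r))
  best <- -Inf
  bestRef <- bestTgt <- 1L
  for (i in seq_along(refAsm)) {
    refProf <- .assemblyProfile(archS, refAsm[[i]])
    for (j in seq_along(tgtAsm)) {
      s <- .profileFas(refProf, tgtProfs[[j]], counts, params)
      if (s > best + 1e-12) {
        best <- s
        bestRef <- i
        bestTgt <- j
      }
    }
  }
  res <- .scorePair(.resolveRows(archS, refAsm[[bestRef]]),
                    .resolveRows(archO, tgtAsm[[bestTgt]]),
                    counts, params, "exhaustive")
  new("SearchOutcome", result = res,
      combinationsEvaluated = length(refAsm) * length(tgtAsm),
      mode = "exhaustive")
}

## ---- priority mode -------------------------------------------------------

# per-instance contribution of candidate instances of `arch` against the
# other protein's full instance set, under weights over arch's full
# (unresolved) type set; used by the greedy junction decisions
.partialContrib <- function(arch, other, counts, params) {
  df <- arch@features
  types <- unique(df$typeId)
  if (length(types) == 0L) return(numeric(0))
  w <- computeWeights(types, counts, params)
  nS <- table(df$typeId)
  odf <- other@features
  oSplit <- split((odf$start + odf$end) / 2 / other@proteinLength, odf$typeId)
  mids <- (df$start + df$end) / 2 / arch@proteinLength
  vapply(seq_len(nrow(df)), function(i) {
    t <- df$typeId[i]
    ns <- as.integer(nS[[t]])
    mo <- oSplit[[t]]
    if (is.null(mo)) return(0)
    (w[[t]] / ns) * (params@alpha * min(length(mo) / ns, 1) +
                       (1 - params@alpha) * (1 - min(abs(mids[i] - mo))))
  }, numeric(1L))
}

# greedy left-to-right resolution of one layer graph; at each junction the
# instance with the largest partial contribution wins, unless an instance
# of `priorityType` is present, which takes precedence
.greedyLayerPath <- function(graph, contrib, priorityType = NULL) {
  sub <- graph@instances
  n <- nrow(sub)
  if (n == 0L) return(integer(0))
  inc <- graph@incompat
  remaining <- seq_len(n)
  selected <- integer(0)
  while (length(remaining)) {
    head <- remaining[1L]
    junction <- remaining[inc[head, remaining] | remaining == head]
    cand <- junction
    if (!is.null(priorityType)) {
      prio <- junction[sub$typeId[junction] == priorityType]
      if (length(prio)) cand <- prio
    }
    win <- cand[which.max(contrib[sub$row[cand]])]
    selected <- c(selected, win)
    remaining <- remaining[!(inc[win, remaining] | remaining == win)]
  }
  sub$row[sort.int(selected)]
}

# candidate realizations for one protein: the greedy path plus one
# priority-t path per feature type with >= 2 instances; deduplicated,
# greedy first, priority types in sorted order
.priorityCandidates <- function(arch, other, counts, params) {
  if (nrow(arch@features) == 0L)
    return(list(greedy = as(arch, "ResolvedArchitecture")))
  contrib <- .partialContrib(arch, other, counts, params)
  graphs <- .layerGraphs(arch, params@maxOverlap)
  assemble <- function(priorityType) {
    rows <- sort.int(unlist(lapply(graphs, .greedyLayerPath, contrib = contrib,
                                   priorityType = priorityType),
                            use.names = FALSE))
    .resolveRows(arch, rows)
  }
  cands <- list(greedy = assemble(NULL))
  multi <- table(arch@features$typeId)
  for (t in sort(names(multi)[multi >= 2L])) {
    cands[[paste0("priority:", t)]] <- assemble(t)
  }
  sig <- vapply(cands, .architectureString, character(1L))
  cands[!duplicated(sig)]
}

#' Priority-mode heuristic search
#'
#' A linear-cost alternative to [exhaustiveSearch()] for highly redundant
#' architectures. Per protein a small candidate set of realizations is
#' built: the *greedy* realization, where each junction between mutually
#' exclusive instances is decided by the instance with the largest weighted
#' partial score contribution against the other protein's full instance set
#' (this is the lower bound), plus one *priority* realization per feature
#' type with at least two instances, in which instances of that type take
#' precedence at junctions. All (reference candidate, target candidate)
#' pairs are scored with [fasScore()] and the maximum is returned, so the
#' priority result is never below the greedy lower bound, and never above
#' the exhaustive maximum.
#'
#' @inheritParams exhaustiveSearch
#' @return A [SearchOutcome-class] with mode `"priority"`.
#' @export
prioritySearch <- function(archS, archO, counts = NULL,
                           params = ScoringParams()) {
  refCands <- .priorityCandidates(archS, archO, counts, params)
  tgtCands <- .priorityCandidates(archO, archS, counts, params)
  best <- NULL
  bestFas <- -Inf
  for (rc in refCands) {
    for (tc in tgtCands) {
      res <- .scorePair(rc, tc, counts, params, "priority")
      if (res@fas > bestFas + 1e-12) {
        bestFas <- res@fas
        best <- res
      }
    }
  }
  new("SearchOutcome", result = best,
      combinationsEvaluated = length(refCands) * length(tgtCands),
      mode = "priority")
}

#' Greedy lower bound of the priority search
#'
#' Scores only the pair of greedy realizations (the first candidates of
#' [prioritySearch()]); by construction `greedy <= priority <= exhaustive`.
#'
#' @inheritParams exhaustiveSearch
#' @return A [ScoreResult-class] with mode `"priority"`.
#' @export
greedyScore <- function(archS, archO, counts = NULL,
                        params = ScoringParams()) {
  refCands <- .priorityCandidates(archS, archO, counts, params)
  tgtCands <- .priorityCandidates(archO, archS, counts, params)
  .scorePair(refCands[[1L]], tgtCands[[1L]], counts, params, "priority")
}

#' Compare two architectures, selecting the search mode automatically
#'
#' Uses the exhaustive search while the number of path combinations does
#' not exceed `params@priorityThreshold` (default 500) and the priority
#' heuristic beyond that.
#'
#' @inheritParams exhaustiveSearch
#' @return A [SearchOutcome-class].
#' @examples
#' s <- randomArchitecture(seed = 1)
#' o <- randomArchitecture(seed = 2)
#' compareArchitectures(s, o)
#' @export
compareArchitectures <- function(archS, archO, counts = NULL,
                                 params = ScoringParams()) {
  combos <- countPathCombinations(archS, archO, params@maxOverlap)
  if (combos <= params@priorityThreshold)
    exhaustiveSearch(archS, archO, counts, params)
  else
    prioritySearch(archS, archO, counts, params)
}

#' Mean bidirectional architecture similarity
#'
#' The FAS score is asymmetric; for applications that need a symmetric
#' measure (ortholog screening, phylogenetic profiles) the two directions
#' are averaged: `(FAS(A,B) + FAS(B,A)) / 2`.
#'
#' @param archA,archB the two [ProteinArchitecture-class] objects.
#' @inheritParams exhaustiveSearch
#' @return Mean bidirectional FAS score in \[0, 1\].
#' @export
bidirectionalMean <- function(archA, archB, counts = NULL,
                              params = ScoringParams()) {
  (fasValue(compareArchitectures(archA, archB, counts, params)) +
     fasValue(compareArchitectures(archB, archA, counts, params))) / 2
}

#' Flag a score as an outlier within an ortholog group
#'
#' A candidate is flagged when its score falls more than two standard
#' deviations below the group mean (strict inequality; sample SD with n-1
#' denominator). Used to spot proteins whose architecture differs
#' significantly from the rest of their group.
#'
#' @param groupScores numeric vector of at least two group scores.
#' @param candidate the score to test.
#' @return `TRUE` iff `candidate < mean(groupScores) - 2 * sd(groupScores)`.
#' @examples
#' flagOutliers(c(0.90, 0.92, 0.88, 0.91), 0.50)   # TRUE
#' @export
flagOutliers <- function(groupScores, candidate) {
  if (length(groupScores) < 2L)
    stop("need at least two group scores to estimate the cut-off")
  candidate < mean(groupScores) - 2 * sd(groupScores)
}
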