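## Per-layer compatibility graphs and enumeration of alternative
## non-redundant paths. A "path" is a MAXIMAL set of pairwise-compatible
## instances of one layer: no further instance of the layer can be added
## without exceeding the overlap cut-off against a selected one. Cross-layer
## overlaps never create incompatibilities.

#' Number of residues shared by two feature instances
#'
#' `max(0, min(endA, endB) - max(startA, startB) + 1)` for 1-based inclusive
#' coordinates; instances meeting end-to-start (e.g. 1-50 and 51-80) share 0
#' residues.
#'
#' @param a,b feature instances, given either as length-2 numeric vectors
#'   `c(start, end)` or as list-likes with `$start`/`$end` (e.g. one row of
#'   [featureTable()]).
#' @return Non-negative integer overlap length.
#' @examples
#' overlapLength(c(1, 50), c(10, 60))   # 41
#' overlapLength(c(1, 50), c(51, 80))   # 0
#' @export
overlapLength <- function(a, b) {
  coords <- function(x) {
    if (is.numeric(x) && length(x) >= 2L) c(x[[1L]], x[[2L]])
    else c(x$start, x$end)
  }
  a <- coords(a); b <- coords(b)
  max(0L, as.integer(min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L))
}

#' Build the compatibility graph of one annotation layer
#'
#' Two same-layer instances are compatible iff they share at most
#' `maxOverlap` residues; instances sharing more are mutually exclusive and
#' give rise to alternative paths. Instances are ordered by (start, end,
#' type), reflecting their order in the protein.
#'
#' @param arch a [ProteinArchitecture-class].
#' @param layerId the layer to extract; must be annotated in `arch`.
#' @param maxOverlap non-negative overlap cut-off in residues (default 0).
#' @return A [LayerGraph-class].
#' @export
buildLayerGraph <- function(arch, layerId, maxOverlap = 0L) {
  stopifnot(is(arch, "ProteinArchitecture"))
  maxOverlap <- as.integer(maxOverlap)
  if (is.na(maxOverlap) || maxOverlap < 0L)
    stop("maxOverlap must be a non-negative integer")
  df <- arch@features
  sel <- which(df$layerId == layerId)
  if (length(sel) == 0L)
    stop("layer \"", layerId, "\" is not annotated in protein ",
         arch@proteinId)
  sub <- df[sel, , drop = FALSE]
  ord <- order(sub$start, sub$end, sub$typeId)
  sub <- sub[ord, , drop = FALSE]
  sub$row <- sel[ord]
  rownames(sub) <- NULL
  n <- nrow(sub)
  inc <- matrix(FALSE, n, n)
  if (n > 1L) {
    ir <- IRanges(start = sub$start, end = sub$end)
    hits <- findOverlaps(ir, drop.self = TRUE, minoverlap = maxOverlap + 1L)
    inc[cbind(queryHits(hits), subjectHits(hits))] <- TRUE
  }
  new("LayerGraph", layerId = layerId, instances = sub, incompat = inc,
      maxOverlap = maxOverlap)
}

# Bron-Kerbosch-style recursion over the compatibility relation; vertices
# are visited in index order so the output is deterministic. `emit` is
# called once per maximal compatible set.
.maximalCompatibleSets <- function(incompat, emit) {
  n <- nrow(incompat)
  if (n == 0L) { emit(integer(0)); return(invisible()) }
  comp <- !incompat
  diag(comp) <- FALSE
  rec <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) { emit(R); return(invisible()) }
    while (length(P)) {
      v <- P[1L]
      nb <- which(comp[v, ])
      rec(c(R, v), P[P %in% nb], X[X %in% nb])
      P <- P[-1L]
      X <- c(X, v)
    }
  }
  rec(integer(0), seq_len(n), integer(0))
  invisible()
}

#' Enumerate the alternative non-redundant paths of a layer
#'
#' Returns exactly the maximal sets of pairwise-compatible instances, i.e.
#' every alternative resolution of the layer's redundant parts. A layer
#' without mutual incompatibilities yields a single path containing all
#' instances. Output order is deterministic (lexicographic in the instance
#' indices of [graphInstances()]).
#'
#' @param graph a [LayerGraph-class].
#' @return List of integer index vectors into `graphInstances(graph)`, each
#'   sorted by position in the protein.
#' @seealso [countLayerPaths()]
#' @export
enumerateLayerPaths <- function(graph) {
  stopifnot(is(graph, "LayerGraph"))
  paths <- list()
  .maximalCompatibleSets(graph@incompat, function(idx) {
    paths[[length(paths) + 1L]] <<- sort.int(idx)
  })
  key <- vapply(paths,
                function(i) paste(sprintf("%09d", i), collapse = ","),
                character(1L))
  paths[order(key)]
}

#' Count the alternative paths of a layer without materializing them
#'
#' Equals `length(enumerateLayerPaths(graph))`; used to decide between the
#' exhaustive search and the priority heuristic.
#'
#' @param graph a [LayerGraph-class].
#' @return Positive integer path count.
#' @export
countLayerPaths <- function(graph) {
  stopifnot(is(graph, "LayerGraph"))
  k <- 0L
  .maximalCompatibleSets(graph@incompat, function(idx) k <<- k + 1L)
  k
}

# per-layer graphs for every annotated layer of an architecture
.layerGraphs <- function(arch, maxOverlap) {
  layers <- sort(unique(arch@features$layerId))
  setNames(lapply(layers, function(l) buildLayerGraph(arch, l, maxOverlap)),
           layers)
}

# enumerated paths per layer, as feature-table row indices
.architecturePaths <- function(arch, maxOverlap) {
  graphs <- .layerGraphs(arch, maxOverlap)
  lapply(graphs, function(g) {
    lapply(enumerateLayerPaths(g), function(idx) g@instances$row[idx])
  })
}

#' Total number of path combinations for a protein pair
#'
#' The product over all layers of both architectures of their per-layer path
#' counts: the size of the search space the exhaustive mode evaluates. An
#' architecture without features contributes a factor of 1.
#'
#' @param archS,archO the two [ProteinArchitecture-class] objects.
#' @param maxOverlap overlap cut-off in residues.
#' @return Path-combination count (double, to allow large products).
#' @export
countPathCombinations <- function(archS, archO, maxOverlap = 0L) {
  one <- function(arch) {
    graphs <- .layerGraphs0(arch, maxOverlap)
    if (length(graphs) == 0L) return(1)
    prod(vapply(graphs, function(g) as.numeric(countLayerPaths(g)), numeric(1L)))
  }
  one(archS) * one(archO)
}

# like .layerGraphs but returns an empty list for an unannotated protein
.layerGraphs0 <- function(arch, maxOverlap) {
  if (nrow(arch@features) == 0L) return(list())
  .layerGraphs(arch, maxOverlap)
}
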