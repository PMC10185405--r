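# Independent oracles, deliberately kept structurally different from the
# package implementation: literal evaluation of the printed score formulas
# on raw feature tables, plus two independent enumerators of the maximal
# compatible instance sets (bitmask brute force over all 2^n subsets, and
# igraph maximal cliques of the compatibility graph).

oracleOverlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)

# literal weight formula including the cancelling numerator sum_l(f(o_l)+1)
oracleWeights <- function(o, transform = log) {
  p <- vapply(o, function(oi) sum(transform(o) + 1) / (transform(oi) + 1),
              numeric(1))
  p / sum(p)
}

oracleMS <- function(ref, tgt, w) {
  ms <- 0
  for (t in unique(ref$typeId)) {
    NS <- sum(ref$typeId == t)
    NO <- sum(tgt$typeId == t)
    if (NO > 0) ms <- ms + w[[t]] * min(NS * NO / NS^2, 1)
  }
  ms
}

oraclePS <- function(ref, tgt, refLen, tgtLen, w) {
  ps <- 0
  for (t in unique(ref$typeId)) {
    ri <- ref[ref$typeId == t, , drop = FALSE]
    ti <- tgt[tgt$typeId == t, , drop = FALSE]
    if (nrow(ti) == 0) next
    Ps <- (ri$start + ri$end) / 2 / refLen
    Po <- (ti$start + ti$end) / 2 / tgtLen
    acc <- 0
    for (p in Ps) acc <- acc + (1 - min(abs(p - Po)))
    ps <- ps + w[[t]] / nrow(ri) * acc
  }
  ps
}

# uniform-weight FAS on two raw feature tables (the acceptance conditions
# use the default: no count table, hence uniform weights)
oracleFas <- function(ref, tgt, refLen, tgtLen, alpha = 0.7) {
  types <- unique(ref$typeId)
  if (length(types) == 0) return(0)
  w <- setNames(rep(1 / length(types), length(types)), types)
  alpha * oracleMS(ref, tgt, w) + (1 - alpha) * oraclePS(ref, tgt, refLen, tgtLen, w)
}

# all maximal sets of pairwise-compatible rows, by testing every subset
bitmaskMaximalSets <- function(sub, maxOverlap = 0) {
  n <- nrow(sub)
  if (n == 0) return(list(integer(0)))
  stopifnot(n <= 15)
  conf <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      conf[i, j] <- oracleOverlap(sub$start[i], sub$end[i],
                                  sub$start[j], sub$end[j]) > maxOverlap
  }
  out <- list()
  for (mask in seq_len(2^n) - 1L) {
    mem <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(mem) > 1 && any(conf[mem, mem])) next
    nonmem <- setdiff(seq_len(n), mem)
    maximal <- all(vapply(nonmem, function(v)
      any(conf[v, mem]), logical(1)))
    if (length(mem) == 0 && n > 0) maximal <- FALSE
    if (maximal || (length(mem) == n))
      out[[length(out) + 1L]] <- mem
  }
  out
}

# same sets via igraph maximal cliques of the compatibility graph
igraphMaximalSets <- function(sub, maxOverlap = 0) {
  n <- nrow(sub)
  if (n == 0) return(list(integer(0)))
  conf <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      conf[i, j] <- oracleOverlap(sub$start[i], sub$end[i],
                                  sub$start[j], sub$end[j]) > maxOverlap
  }
  comp <- !conf
  diag(comp) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(comp, mode = "undirected")
  lapply(igraph::max_cliques(g), function(cl) sort(as.integer(cl)))
}

# every assembled realization (one maximal set per layer) of an architecture
oracleAssemblies <- function(arch, maxOverlap = 0,
                             enumerate = igraphMaximalSets) {
  df <- featureTable(arch)
  if (nrow(df) == 0) return(list(df))
  layers <- unique(df$layerId)
  perLayer <- lapply(layers, function(l) {
    sub <- df[df$layerId == l, , drop = FALSE]
    lapply(enumerate(sub, maxOverlap), function(s) sub[s, , drop = FALSE])
  })
  grid <- expand.grid(lapply(perLayer, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    do.call(rbind, lapply(seq_along(perLayer),
                          function(j) perLayer[[j]][[grid[i, j]]]))
  })
}

# brute-force maximum FAS over all pairs of assembled realizations
oracleBestFas <- function(archS, archO, maxOverlap = 0, alpha = 0.7) {
  refAsms <- oracleAssemblies(archS, maxOverlap)
  tgtAsms <- oracleAssemblies(archO, maxOverlap)
  best <- -Inf
  for (ra in refAsms) {
    for (ta in tgtAsms) {
      s <- oracleFas(ra, ta, proteinLength(archS), proteinLength(archO),
                     alpha)
      if (s > best) best <- s
    }
  }
  best
}
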