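# Shared fixtures. The seeded pair suite emulates diverging ortholog pairs:
# a random multi-layered architecture plus a perturbed partner with feature
# loss, duplication, positional drift and redundant decoy annotation. Pairs
# are kept when their path-combination count is at most 2000 so the
# brute-force oracle stays tractable. Everything is a pure function of the
# fixed base seed.

makeArch <- function(id, len, ...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(layerId = r[["layer"]], typeId = r[["type"]],
               start = as.integer(r[["start"]]), end = as.integer(r[["end"]]),
               evalue = if (is.null(r[["evalue"]])) NA_real_
                        else as.numeric(r[["evalue"]]),
               stringsAsFactors = FALSE)))
  ProteinArchitecture(id, len, df)
}

inst <- function(layer, type, start, end, evalue = NULL) {
  list(layer = layer, type = type, start = start, end = end, evalue = evalue)
}

seededPairSuite <- local({
  cache <- NULL
  function(n = 500L, baseSeed = 20260101L) {
    if (!is.null(cache) && length(cache) >= n) return(cache[seq_len(n)])
    pairs <- vector("list", n)
    i <- 0L
    seed <- baseSeed
    while (i < n) {
      seed <- seed + 2L
      s <- randomArchitecture(nLayers = 2, nTypes = 3, nInstances = 4,
                              length = 120, seed = seed,
                              proteinId = paste0("S", seed))
      o <- perturbArchitecture(s, PerturbationSpec(pLoss = 0.2, pDup = 0.2,
                                                   shiftSd = 0.03,
                                                   pRedundant = 0.4,
                                                   seed = seed + 1L))
      o@proteinId <- paste0("O", seed)
      if (countPathCombinations(s, o) > 2000) next
      i <- i + 1L
      pairs[[i]] <- list(s = s, o = o)
    }
    cache <<- pairs
    pairs
  }
})

# scores of all strategies over the seeded suite, computed once and shared
# by several tests
suiteScores <- local({
  cache <- NULL
  function(n = 500L) {
    if (!is.null(cache) && nrow(cache) >= n) return(cache[seq_len(n), ])
    pairs <- seededPairSuite(n)
    rows <- lapply(pairs, function(p) {
      ex <- exhaustiveSearch(p$s, p$o)
      pr <- prioritySearch(p$s, p$o)
      data.frame(
        combos = countPathCombinations(p$s, p$o),
        exh = fasValue(ex), exh_ms = msValue(ex), exh_ps = psValue(ex),
        oracle = oracleBestFas(p$s, p$o),
        pri = fasValue(pr),
        greedy = fasValue(greedyScore(p$s, p$o)),
        ev = fasValue(scoreByEvalue(p$s, p$o)),
        unres = fasValue(scoreUnresolved(p$s, p$o)))
    })
    cache <<- do.call(rbind, rows)
    cache
  }
})

# crafted pairs where the unresolved baseline over- resp. under-estimates
# the score-maximized similarity: redundant agreeing annotations buffer a
# missing feature (over), while redundant disagreeing annotations dilute
# the shared ones (under)
unresolvedBiasFixtures <- function() {
  over <- list(
    s = makeArch("ovS", 200,
                 inst("pfam_smart", "pfam:A", 10, 60, 1e-10),
                 inst("pfam_smart", "pfam:B", 20, 70, 1e-5),
                 inst("pfam_smart", "pfam:D", 120, 170, 1e-8)),
    o = makeArch("ovO", 200,
                 inst("pfam_smart", "pfam:A", 10, 60, 1e-9),
                 inst("pfam_smart", "pfam:B", 100, 150, 1e-9)))
  under <- list(
    s = makeArch("unS", 200,
                 inst("pfam_smart", "pfam:A", 10, 60, 1e-10),
                 inst("pfam_smart", "pfam:B", 20, 70, 1e-5),
                 inst("pfam_smart", "pfam:C", 120, 170, 1e-8)),
    o = makeArch("unO", 200,
                 inst("pfam_smart", "pfam:C", 120, 170, 1e-9)))
  list(over = over, under = under)
}

# strict sub-architecture: every reference type occurs in the target with at
# least as many instances at identical relative midpoints; the target has an
# extra type of its own
subArchitectureFixture <- function() {
  s <- makeArch("sub", 200,
                inst("pfam_smart", "pfam:A", 21, 60, 1e-10),   # mid 0.2025
                inst("seg", "seg:lc", 101, 140))               # mid 0.6025
  o <- makeArch("super", 400,
                inst("pfam_smart", "pfam:A", 41, 121, 1e-9),   # mid 0.2025
                inst("seg", "seg:lc", 201, 281),               # mid 0.6025
                inst("pfam_smart", "pfam:X", 321, 381, 1e-6))
  list(s = s, o = o)
}
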