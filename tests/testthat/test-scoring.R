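# Feature weighting and the multiplicity / positional / combined scores.

test_that("uniform weights split the mass evenly", {
  w <- computeWeights(c("a", "b", "c", "d"))
  expect_equal(unname(w), rep(0.25, 4))
  expect_equal(sum(w), 1)
})

test_that("abundance weighting follows the literal weight formula", {
  # equal abundances are symmetric
  wEq <- computeWeights(c("a", "b"), FeatureCounts(c(a = 1, b = 1)),
                        ScoringParams(weighting = "ln"))
  expect_equal(unname(wEq), c(0.5, 0.5))
  # o = (1, 100): cross-check against the printed formula including the
  # cancelling numerator sum_l(ln(o_l)+1)
  w <- computeWeights(c("a", "b"), FeatureCounts(c(a = 1, b = 100)),
                      ScoringParams(weighting = "ln"))
  expect_equal(unname(w), unname(oracleWeights(c(1, 100))), tolerance = 1e-12)
  expect_equal(unname(w), c(0.8486, 0.1514), tolerance = 1e-4)
  # every transform agrees with its literal evaluation
  o <- c(a = 3, b = 250, c = 41)
  transforms <- list(ln = log, linear = identity, log10 = log10,
                     root4 = function(x) x^0.25, root8 = function(x) x^0.125)
  for (scheme in names(transforms)) {
    w <- computeWeights(names(o), FeatureCounts(o),
                        ScoringParams(weighting = scheme))
    expect_equal(unname(w), unname(oracleWeights(o, transforms[[scheme]])),
                 tolerance = 1e-12, info = scheme)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("weights decrease with abundance; linear penalizes common types most", {
  o <- FeatureCounts(c(rare = 2, mid = 50, common = 5000))
  rel <- sapply(c("linear", "ln", "root4", "log10", "root8"), function(scheme) {
    computeWeights(names(featureCounts(o)), o,
                   ScoringParams(weighting = scheme))[["common"]]
  })
  for (scheme in names(rel)) {
    w <- computeWeights(names(featureCounts(o)), o,
                        ScoringParams(weighting = scheme))
    expect_true(w[["rare"]] > w[["mid"]], info = scheme)
    expect_true(w[["mid"]] > w[["common"]], info = scheme)
  }
  # the common type keeps the least weight under linear, the most under root8
  expect_equal(names(rel)[which.min(rel)], "linear")
  expect_equal(names(rel)[which.max(rel)], "root8")
})

test_that("weighting defaults: uniform without counts, ln with counts", {
  expect_equal(unname(computeWeights(c("a", "b"))), c(0.5, 0.5))
  withCounts <- computeWeights(c("a", "b"), FeatureCounts(c(a = 1, b = 100)))
  expect_equal(unname(withCounts), unname(oracleWeights(c(1, 100))),
               tolerance = 1e-12)
  expect_error(computeWeights(c("a"), NULL, ScoringParams(weighting = "ln")),
               "count table")
  expect_error(computeWeights(character(0)), "empty")
  expect_warning(
    w <- computeWeights(c("a", "b"), FeatureCounts(c(a = 10)),
                        ScoringParams(weighting = "ln")),
    "assuming count 1")
  expect_gt(w[["b"]], w[["a"]])   # missing type gets the conservative count 1
})

test_that("minimum-weight floors hold and mass is conserved", {
  counts <- FeatureCounts(c(tm = 9000, a = 5, b = 7))
  params <- ScoringParams(weighting = "ln", minWeights = c(tm = 0.3))
  w <- computeWeights(c("tm", "a", "b"), counts, params)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gte(w[["tm"]], 0.3)
  # unfloored types keep their relative proportions
  w0 <- computeWeights(c("tm", "a", "b"), counts,
                       ScoringParams(weighting = "ln"))
  expect_equal(w[["a"]] / w[["b"]], w0[["a"]] / w0[["b"]], tolerance = 1e-12)
  # a floor below the natural weight changes nothing
  wLoose <- computeWeights(c("tm", "a", "b"), counts,
                           ScoringParams(weighting = "ln",
                                         minWeights = c(a = 0.01)))
  expect_equal(wLoose, w0, tolerance = 1e-12)
  expect_error(ScoringParams(minWeights = c(a = 0.6, b = 0.5)), "< 1")
})

test_that("multiplicity score evaluates the copy-number formula with its cap", {
  # identical architectures score 1
  a <- as(makeArch("a", 100, inst("pfam", "pfam:A", 10, 20, 1e-3),
                   inst("pfam", "pfam:B", 40, 60, 1e-3)),
          "ResolvedArchitecture")
  wAB <- c("pfam:A" = 0.5, "pfam:B" = 0.5)
  expect_equal(multiplicityScore(a, a, wAB), 1)
  # N^S = 2, N^O = 1: min(2*1/4, 1) = 0.5
  s2 <- as(makeArch("s", 100, inst("pfam", "pfam:A", 10, 20, 1e-3),
                    inst("pfam", "pfam:A", 40, 50, 1e-3)),
           "ResolvedArchitecture")
  o1 <- as(makeArch("o", 100, inst("pfam", "pfam:A", 10, 20, 1e-3)),
           "ResolvedArchitecture")
  expect_equal(multiplicityScore(s2, o1, c("pfam:A" = 1)), 0.5)
  # N^S = 1, N^O = 3 hits the upper bound of 1
  o3 <- as(makeArch("o", 100, inst("pfam", "pfam:A", 10, 20, 1e-3),
                    inst("pfam", "pfam:A", 40, 50, 1e-3),
                    inst("pfam", "pfam:A", 70, 80, 1e-3)),
           "ResolvedArchitecture")
  expect_equal(multiplicityScore(o1, o3, c("pfam:A" = 1)), 1)
  expect_equal(multiplicityScore(s2, o1, c("pfam:A" = 1)),
               oracleMS(featureTable(s2), featureTable(o1), c("pfam:A" = 1)))
})

test_that("positional score matches nearest relative midpoints", {
  # ref midpoint 0.30 against targets at 0.50 and 0.95: PS = 1 - 0.20
  s <- as(makeArch("s", 100, inst("pfam", "pfam:A", 25, 35, 1e-3)),
          "ResolvedArchitecture")
  o <- as(makeArch("o", 100, inst("pfam", "pfam:A", 45, 55, 1e-3),
                   inst("pfam", "pfam:A", 90, 100, 1e-3)),
          "ResolvedArchitecture")
  expect_equal(positionalScore(s, o, c("pfam:A" = 1)), 0.8)
  expect_equal(positionalScore(s, o, c("pfam:A" = 1)),
               oraclePS(featureTable(s), featureTable(o), 100, 100,
                        c("pfam:A" = 1)))
  # identical architectures on equal-length proteins: PS = 1
  expect_equal(positionalScore(o, o, c("pfam:A" = 1)), 1)
  # type absent from the target contributes 0
  x <- as(makeArch("x", 100, inst("pfam", "pfam:B", 10, 20, 1e-3)),
          "ResolvedArchitecture")
  expect_equal(positionalScore(s, x, c("pfam:A" = 1)), 0)
})

test_that("fasScore combines MS and PS linearly and flags empty references", {
  s2 <- makeArch("s", 100, inst("pfam", "pfam:A", 10, 20, 1e-3),
                 inst("pfam", "pfam:A", 40, 50, 1e-3))
  o1 <- makeArch("o", 100, inst("pfam", "pfam:A", 10, 20, 1e-3))
  res <- fasScore(s2, o1)
  expect_equal(fasValue(res),
               0.7 * msValue(res) + 0.3 * psValue(res), tolerance = 1e-12)
  half <- fasScore(s2, o1, params = ScoringParams(alpha = 0.5))
  expect_equal(fasValue(half),
               0.5 * msValue(half) + 0.5 * psValue(half), tolerance = 1e-12)
  # no shared feature types: FAS = 0
  x <- makeArch("x", 100, inst("pfam", "pfam:B", 10, 20, 1e-3))
  expect_equal(fasValue(fasScore(s2, x)), 0)
  # empty reference: score 0 with a flag, not an error
  emptyRes <- fasScore(ProteinArchitecture("e", 50), o1)
  expect_equal(fasValue(emptyRes), 0)
  expect_true("empty-reference" %in% scoreFlags(emptyRes))
})

test_that("resolveByEvalue keeps minimal e-values and yields a maximal path", {
  arch <- makeArch("p", 120,
                   inst("pfam", "pfam:A", 1, 50, 1e-10),
                   inst("pfam", "pfam:B", 10, 60, 1e-3),
                   inst("pfam", "pfam:C", 55, 100, 1e-6))
  r <- resolveByEvalue(arch, 0)
  expect_setequal(featureTable(r)$typeId, c("pfam:A", "pfam:C"))
  # non-overlapping instances all survive
  clean <- makeArch("q", 120, inst("pfam", "pfam:A", 1, 20, 1e-3),
                    inst("pfam", "pfam:B", 30, 50, 1e-9))
  expect_equal(nrow(featureTable(resolveByEvalue(clean, 0))), 2L)
  # instances without e-values rank after those with e-values
  mix <- makeArch("m", 120,
                  inst("pfam", "pfam:A", 1, 50, 1e-5),
                  inst("pfam", "pfam:B", 10, 60))
  expect_equal(featureTable(resolveByEvalue(mix, 0))$typeId, "pfam:A")
  # the result is one of the enumerated maximal paths
  fx <- figure1Fixture()
  rf <- resolveByEvalue(fx$ref, 0)
  asmKeys <- vapply(oracleAssemblies(fx$ref, 0),
                    function(a) paste(a$typeId, a$start, collapse = "|"), "")
  rfDf <- featureTable(rf)
  expect_true(paste(rfDf$typeId, rfDf$start, collapse = "|") %in% asmKeys)
})

test_that("unresolved scoring uses the complete overlapping instance sets", {
  # ref type annotated redundantly by 3 overlapping variants, tgt by 1:
  # the MS term for that type is min(3*1/9, 1) = 1/3
  s <- makeArch("s", 100, inst("pfam", "pfam:A", 10, 40, 1e-9),
                inst("pfam", "pfam:A", 12, 42, 1e-7),
                inst("pfam", "pfam:A", 14, 44, 1e-5))
  o <- makeArch("o", 100, inst("pfam", "pfam:A", 10, 40, 1e-8))
  res <- scoreUnresolved(s, o)
  expect_equal(msValue(res), 1 / 3)
  expect_equal(searchMode(res), "baseline_unresolved")
  expect_null(resolvedReference(res))
  # non-redundant architectures: identical to the exhaustive search
  clean <- makeArch("c", 100, inst("pfam", "pfam:A", 10, 30, 1e-9),
                    inst("seg", "seg:lc", 50, 80))
  expect_equal(fasValue(scoreUnresolved(clean, clean)),
               fasValue(exhaustiveSearch(clean, clean)))
  # empty target scores 0
  expect_equal(fasValue(scoreUnresolved(s, ProteinArchitecture("e", 50))), 0)
})

test_that("targets lacking a reference type never gain from deletion", {
  # removing a shared type from the target can only lower MS and FAS
  for (seed in 501:510) {
    pair <- seededPairSuite(30)[[seed %% 30 + 1]]
    sR <- as(pair$s, "ResolvedArchitecture")
    oR <- as(pair$o, "ResolvedArchitecture")
    shared <- intersect(typeIds(pair$s), typeIds(pair$o))
    if (length(shared) == 0) next
    w <- computeWeights(typeIds(sR))
    msFull <- multiplicityScore(sR, oR, w)
    oDf <- featureTable(pair$o)
    oDel <- ProteinArchitecture(proteinId(pair$o), proteinLength(pair$o),
                                oDf[oDf$typeId != shared[1], , drop = FALSE])
    msDel <- multiplicityScore(sR, as(oDel, "ResolvedArchitecture"), w)
    expect_lte(msDel, msFull + 1e-12)
  }
})
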