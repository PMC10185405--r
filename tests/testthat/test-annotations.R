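# Annotation model and file I/O: native JSON dialect, InterProScan TSV
# adapter, count tables, and the layer-merging convention.

test_that("native JSON round-trips a single-instance architecture", {
  arch <- makeArch("p1", 100, inst("pfam", "pfam:PF00515", 10, 50, 1e-8))
  path <- withr::local_tempfile(fileext = ".json")
  writeAnnotations(list(arch), path)
  back <- readAnnotations(path, ScoringParams(mergePfamSmart = FALSE))
  expect_named(back, "p1")
  expect_equal(featureTable(back$p1), featureTable(arch))
  expect_equal(proteinLength(back$p1), 100L)
})

test_that("round trip preserves multi-layer architectures with and without e-values", {
  archs <- lapply(1:4, function(i)
    randomArchitecture(nLayers = 3, nTypes = 2, nInstances = 3,
                       length = 150, seed = 400 + i))
  path <- withr::local_tempfile(fileext = ".json")
  writeAnnotations(archs, path)
  back <- readAnnotations(path, ScoringParams(mergePfamSmart = FALSE))
  for (a in archs) {
    expect_equal(featureTable(back[[proteinId(a)]]), featureTable(a))
    expect_equal(proteinLength(back[[proteinId(a)]]), proteinLength(a))
  }
})

test_that("pfam and smart layers merge into pfam_smart without losing instances", {
  arch <- makeArch("p1", 200,
                   inst("pfam", "pfam:PF00515", 10, 50, 1e-8),
                   inst("smart", "smart:SM00028", 30, 70, 1e-5),
                   inst("seg", "seg:lc", 100, 130))
  path <- withr::local_tempfile(fileext = ".json")
  writeAnnotations(list(arch), path)
  merged <- readAnnotations(path)$p1
  expect_equal(nrow(featureTable(merged)), 3L)
  expect_setequal(layerIds(merged), c("pfam_smart", "seg"))
  # type identity is kept verbatim; only the layer assignment changes
  expect_setequal(typeIds(merged), typeIds(arch))
  pf <- featureTable(merged)
  expect_equal(sum(pf$layerId == "pfam_smart"), 2L)
})

test_that("validation rejects instances beyond the protein and duplicate ids", {
  expect_error(makeArch("p1", 100, inst("pfam", "pfam:PF1", 90, 120, 1e-3)),
               "exceeds protein length")
  expect_error(ProteinArchitecture("p1", 0), "positive")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"proteins": {"p1": {"length": 50, "features": {}},',
                    ' "p1": {"length": 60, "features": {}}}}'), path)
  expect_error(readAnnotations(path), "duplicate protein_id")
  writeLines('{"proteins": {"p1": {"length": 50, ', path)
  expect_error(readAnnotations(path), "malformed JSON")
})

test_that("InterProScan TSV rows map to instances; unmapped analyses are skipped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    paste("prot1", "md5", "200", "Pfam", "PF00515", "TPR repeat",
          "34", "67", "1e-8", "T", "01-01-2024", sep = "\t"),
    paste("prot1", "md5", "200", "Pfam", "PF00515", "TPR repeat",
          "90", "130", "2e-4", "T", "01-01-2024", sep = "\t"),
    paste("prot1", "md5", "200", "MobiDBLite", "mobidb-lite", "disorder",
          "150", "180", "-", "T", "01-01-2024", sep = "\t"),
    paste("prot2", "md5", "120", "SMART", "SM00028", "TPR",
          "10", "44", "3e-6", "T", "01-01-2024", sep = "\t"))
  writeLines(rows, path)
  expect_warning(
    archs <- readInterproscanTsv(path, params = ScoringParams(mergePfamSmart = FALSE)),
    "MobiDBLite")
  p1 <- featureTable(archs$prot1)
  expect_equal(nrow(p1), 2L)               # multiplicity preserved, unmapped dropped
  expect_equal(p1$typeId, rep("pfam:PF00515", 2))
  expect_equal(p1$start, c(34L, 90L))
  expect_equal(p1$evalue, c(1e-8, 2e-4))
  expect_equal(proteinLength(archs$prot1), 200L)
  p2 <- featureTable(archs$prot2)
  expect_equal(p2$typeId, "smart:SM00028")
  expect_equal(p2$layerId, "smart")
})

test_that("InterProScan parser rejects short tables and bad coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("prot1", "md5", "200", "Pfam", sep = "\t"), path)
  expect_error(readInterproscanTsv(path), "11 columns")
  writeLines(c(
    paste("p", "m", "200", "Pfam", "PF1", "d", "xx", "67", "1e-8", "T", "d",
          sep = "\t"),
    paste("p", "m", "200", "Pfam", "PF2", "d", "10", "30", "1e-8", "T", "d",
          sep = "\t")), path)
  expect_warning(archs <- readInterproscanTsv(path), "non-numeric start/stop")
  expect_equal(nrow(featureTable(archs$p)), 1L)
})

test_that("count tables read, validate and reject bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pfam:PF00515\t412", "seg:lc\t9000"), path)
  ct <- readCountTable(path)
  expect_equal(featureCounts(ct)[["pfam:PF00515"]], 412L)
  expect_equal(featureCounts(ct)[["seg:lc"]], 9000L)
  writeLines(c("pfam:PF00515\t412", "pfam:PF00515\t3"), path)
  expect_error(readCountTable(path), "duplicate")
  writeLines("pfam:PF00515\t0", path)
  expect_error(readCountTable(path), "positive")
  expect_error(readCountTable(file.path(tempdir(), "absent.tsv")), "not found")
})

test_that("countFeatures sums instances per type and is additive over proteomes", {
  a1 <- makeArch("a", 100, inst("pfam", "pfam:A", 1, 10, 1e-3),
                 inst("pfam", "pfam:A", 20, 30, 1e-3),
                 inst("pfam", "pfam:B", 40, 50, 1e-3))
  a2 <- makeArch("b", 100, inst("pfam", "pfam:A", 1, 10, 1e-3))
  expect_equal(featureCounts(countFeatures(list(a1))),
               c("pfam:A" = 2L, "pfam:B" = 1L))
  both <- featureCounts(countFeatures(list(a1, a2)))
  expect_equal(both[["pfam:A"]], 3L)
  # additivity across proteome halves
  c1 <- featureCounts(countFeatures(list(a1)))
  c2 <- featureCounts(countFeatures(list(a2)))
  types <- union(names(c1), names(c2))
  summed <- setNames(vapply(types, function(t)
    sum(c1[t], c2[t], na.rm = TRUE), numeric(1)), types)
  expect_equal(as.numeric(both[types]), as.numeric(summed))
  expect_error(countFeatures(list()), "empty")
  expect_error(countFeatures(list(ProteinArchitecture("e", 50))),
               "no feature instances")
})
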