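## Batch comparison driver and output writers. This is the programmatic
## surface behind the command-line wrapper in inst/scripts/fas-compare.R.

.fmtScore <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))

#' Score protein pairs from annotation files and write a result TSV
#'
#' Reads reference and target annotation files (native JSON, see
#' [readAnnotations()]), pairs the proteins, runs
#' [compareArchitectures()] on each pair and writes
#' `<outputPrefix>.tsv` with columns `ref_id`, `tgt_id`, `MS`, `PS`,
#' `FAS`, `mode`, `combinations`, `ref_resolved`, `tgt_resolved`
#' (realizations as `layer/type:start-end;...`), optionally `FAS_F`,
#' `FAS_R`, `FAS_mean` (bidirectional), `FAS_evalue`, `FAS_unresolved`
#' (baselines), and `errors`. Scores are printed with 4 decimals;
#' identical inputs give byte-identical outputs. Per-pair failures are
#' reported in the `errors` column instead of aborting the run.
#'
#' @param refAnnotations,tgtAnnotations paths to annotation JSON files.
#' @param outputPrefix path prefix for output files.
#' @param pairs optional two-column data.frame or TSV path (`ref_id`,
#'   `tgt_id`); by default proteins are paired by identical id (or all
#'   against all with `allVsAll = TRUE`). Pairs naming unknown proteins are
#'   skipped with a warning.
#' @param countTable optional [FeatureCounts-class] or count-table TSV path.
#' @param params a [ScoringParams-class].
#' @param bidirectional also score the reverse direction and report the
#'   mean.
#' @param baselines also report the e-value-resolved and unresolved
#'   baseline scores (forward direction).
#' @param phyloProfile additionally write
#'   `<outputPrefix>.phyloprofile.tsv` (implies `bidirectional`); requires
#'   `taxa`.
#' @param taxa named character vector (or 2-column TSV path) mapping target
#'   protein ids to taxon labels, for the phylogenetic-profile output.
#' @param allVsAll score every reference against every target instead of
#'   matching ids.
#' @return Invisibly, the result data.frame (unformatted scores).
#' @export
runFas <- function(refAnnotations, tgtAnnotations, outputPrefix,
                   pairs = NULL, countTable = NULL,
                   params = ScoringParams(), bidirectional = FALSE,
                   baselines = FALSE, phyloProfile = FALSE, taxa = NULL,
                   allVsAll = FALSE) {
  refs <- readAnnotations(refAnnotations, params)
  tgts <- readAnnotations(tgtAnnotations, params)
  counts <- if (is.character(countTable)) readCountTable(countTable)
            else countTable
  if (phyloProfile) bidirectional <- TRUE
  if (is.character(pairs)) {
    tab <- read.delim(pairs, header = FALSE, sep = "\t",
                      colClasses = "character", stringsAsFactors = FALSE)
    pairs <- data.frame(ref_id = tab[[1L]], tgt_id = tab[[2L]],
                        stringsAsFactors = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- if (allVsAll)
      expand.grid(ref_id = names(refs), tgt_id = names(tgts),
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    else {
      shared <- intersect(names(refs), names(tgts))
      data.frame(ref_id = shared, tgt_id = shared, stringsAsFactors = FALSE)
    }
  }
  known <- pairs$ref_id %in% names(refs) & pairs$tgt_id %in% names(tgts)
  if (any(!known)) {
    warning("skipping ", sum(!known), " pair(s) with unknown protein ids")
    pairs <- pairs[known, , drop = FALSE]
  }
  if (nrow(pairs) == 0L)
    warning("no protein pairs to score; writing header-only output")

  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    rid <- pairs$ref_id[k]; tid <- pairs$tgt_id[k]
    rows[[k]] <- tryCatch({
      out <- compareArchitectures(refs[[rid]], tgts[[tid]], counts, params)
      res <- scoreResult(out)
      row <- data.frame(ref_id = rid, tgt_id = tid,
                        MS = res@ms, PS = res@ps, FAS = res@fas,
                        mode = searchMode(out),
                        combinations = combinationsEvaluated(out),
                        ref_resolved = .architectureString(res@refPath),
                        tgt_resolved = .architectureString(res@tgtPath),
                        stringsAsFactors = FALSE)
      if (bidirectional) {
        rev <- compareArchitectures(tgts[[tid]], refs[[rid]], counts, params)
        row$FAS_F <- res@fas
        row$FAS_R <- fasValue(rev)
        row$FAS_mean <- (row$FAS_F + row$FAS_R) / 2
      }
      if (baselines) {
        row$FAS_evalue <- fasValue(scoreByEvalue(refs[[rid]], tgts[[tid]],
                                                 counts, params))
        row$FAS_unresolved <- fasValue(scoreUnresolved(refs[[rid]], tgts[[tid]],
                                                       counts, params))
      }
      row$errors <- ""
      row
    }, error = function(e) {
      warning("pair ", rid, " / ", tid, " failed: ", conditionMessage(e))
      row <- data.frame(ref_id = rid, tgt_id = tid, MS = NA_real_,
                        PS = NA_real_, FAS = NA_real_, mode = "error",
                        combinations = NA_real_, ref_resolved = "",
                        tgt_resolved = "", stringsAsFactors = FALSE)
      if (bidirectional) row[c("FAS_F", "FAS_R", "FAS_mean")] <- NA_real_
      if (baselines) row[c("FAS_evalue", "FAS_unresolved")] <- NA_real_
      row$errors <- conditionMessage(e)
      row
    })
  }
  cols <- c("ref_id", "tgt_id", "MS", "PS", "FAS", "mode", "combinations",
            "ref_resolved", "tgt_resolved",
            if (bidirectional) c("FAS_F", "FAS_R", "FAS_mean"),
            if (baselines) c("FAS_evalue", "FAS_unresolved"), "errors")
  result <- if (length(rows)) do.call(rbind, rows)[, cols, drop = FALSE]
            else setNames(as.data.frame(rep(list(character(0)), length(cols)),
                                        stringsAsFactors = FALSE), cols)
  printed <- result
  for (col in intersect(c("MS", "PS", "FAS", "FAS_F", "FAS_R", "FAS_mean",
                          "FAS_evalue", "FAS_unresolved"), names(printed)))
    printed[[col]] <- .fmtScore(result[[col]])
  write.table(printed, paste0(outputPrefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (phyloProfile) {
    if (is.character(taxa) && length(taxa) == 1L && is.null(names(taxa))) {
      tab <- read.delim(taxa, header = FALSE, sep = "\t",
                        colClasses = "character", stringsAsFactors = FALSE)
      taxa <- setNames(tab[[2L]], tab[[1L]])
    }
    writePhyloProfile(result, taxa, paste0(outputPrefix, ".phyloprofile.tsv"))
  }
  invisible(result)
}

#' Write a phylogenetic-profile TSV
#'
#' Produces the minimal tab-separated input of phylogenetic-profile
#' viewers: header `geneID`, `ncbiID`, `orthoID`, `FAS_F`, `FAS_R`, one row
#' per scored pair, scores with 4 decimals.
#'
#' @param results data.frame with columns `ref_id`, `tgt_id`, `FAS_F`,
#'   `FAS_R` (as returned by [runFas()] with `bidirectional = TRUE`).
#' @param taxa named character vector mapping every target id to a taxon
#'   label.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePhyloProfile <- function(results, taxa, path) {
  need <- c("ref_id", "tgt_id", "FAS_F", "FAS_R")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "))
  missing <- setdiff(unique(results$tgt_id), names(taxa))
  if (length(missing))
    stop("no taxon label for target id(s): ", paste(missing, collapse = ", "))
  out <- data.frame(geneID = results$ref_id,
                    ncbiID = unname(taxa[results$tgt_id]),
                    orthoID = results$tgt_id,
                    FAS_F = .fmtScore(results$FAS_F),
                    FAS_R = .fmtScore(results$FAS_R),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
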