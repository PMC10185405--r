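## Annotation input/output: native JSON dialect, InterProScan 5 TSV adapter,
## and the feature-abundance count table.
##
## Native JSON dialect:
##   {"proteins": {"<id>": {"length": <int>, "features":
##       {"<layer>": {"<type_id>": {"instances": [[start, end, evalue|null], ...]}}}}}}

.mergePfamSmartLayers <- function(df) {
  df$layerId[df$layerId %in% c("pfam", "smart")] <- "pfam_smart"
  df
}

#' Read architectures from the native annotation JSON
#'
#' Parses pre-computed per-protein feature annotations. Feature classes that
#' carry no e-values (SEG, fLPS, COILS, tmhmm predictions) use `null` in the
#' instance triplets. With `params@mergePfamSmart` (the default) the
#' `"pfam"` and `"smart"` layers are merged into a single `"pfam_smart"`
#' layer; type identities are kept verbatim, only the layer assignment
#' changes.
#'
#' @param path path to an annotation JSON file.
#' @param params a [ScoringParams-class]; only `mergePfamSmart` is consulted.
#' @return Named list of [ProteinArchitecture-class] objects, one per
#'   protein.
#' @seealso [writeAnnotations()], [readInterproscanTsv()]
#' @export
readAnnotations <- function(path, params = ScoringParams()) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  prots <- doc$proteins
  if (is.null(prots)) stop("annotation file lacks a top-level \"proteins\" object")
  ids <- names(prots)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every protein record needs a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate protein_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    rec <- prots[[id]]
    len <- rec$length
    if (is.null(len) || !is.numeric(len) || len < 1)
      stop("protein ", id, ": missing or invalid length")
    rows <- list()
    for (layer in names(rec$features)) {
      for (type in names(rec$features[[layer]])) {
        inst <- rec$features[[layer]][[type]]$instances
        for (iv in inst) {
          if (length(iv) < 2L || !is.numeric(iv[[1L]]) || !is.numeric(iv[[2L]]))
            stop("protein ", id, ", type ", type,
                 ": instances must be [start, end, evalue|null] triplets")
          ev <- if (length(iv) >= 3L && !is.null(iv[[3L]])) as.numeric(iv[[3L]])
                else NA_real_
          rows[[length(rows) + 1L]] <-
            data.frame(layerId = layer, typeId = type,
                       start = as.integer(iv[[1L]]), end = as.integer(iv[[2L]]),
                       evalue = ev, stringsAsFactors = FALSE)
        }
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else emptyFeatureTable()
    if (params@mergePfamSmart) df <- .mergePfamSmartLayers(df)
    out[[id]] <- tryCatch(ProteinArchitecture(id, len, df),
                          error = function(e)
                            stop("protein ", id, ": ", conditionMessage(e),
                                 call. = FALSE))
  }
  out
}

#' Write architectures to the native annotation JSON
#'
#' Inverse of [readAnnotations()]; `readAnnotations(writeAnnotations(x))`
#' round-trips to an equal structure (layer merging is applied on read, so
#' write after merging or read with `mergePfamSmart = FALSE`).
#'
#' @param architectures named list of [ProteinArchitecture-class] objects
#'   (names are ignored; the stored `proteinId`s are used).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(architectures, path) {
  prots <- list()
  for (arch in architectures) {
    stopifnot(is(arch, "ProteinArchitecture"))
    df <- arch@features
    feats <- list()
    if (nrow(df)) {
      for (layer in unique(df$layerId)) {
        sub <- df[df$layerId == layer, , drop = FALSE]
        byType <- list()
        for (type in unique(sub$typeId)) {
          tt <- sub[sub$typeId == type, , drop = FALSE]
          byType[[type]] <- list(instances = lapply(seq_len(nrow(tt)), function(i) {
            ev <- tt$evalue[i]
            list(tt$start[i], tt$end[i], if (is.na(ev)) NULL else ev)
          }))
        }
        feats[[layer]] <- byType
      }
    }
    prots[[arch@proteinId]] <- list(length = arch@proteinLength,
                                    features = feats)
  }
  json <- jsonlite::toJSON(list(proteins = prots), auto_unbox = TRUE,
                           null = "null", digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read architectures from an InterProScan 5 TSV
#'
#' Consumes the standard tab-separated InterProScan output (>= 11 columns:
#' accession, md5, length, analysis, signature id, description, start, stop,
#' score, status, date). Each row becomes one feature instance
#' `tolower(analysis):signature` in the layer given by `layerMap`; rows from
#' analyses without a `layerMap` entry are skipped with a warning, as are
#' rows with non-numeric coordinates. The score column is used as the
#' e-value when numeric.
#'
#' @param path path to the TSV file.
#' @param layerMap named character vector mapping analysis names to layer
#'   ids, e.g. `c(Pfam = "pfam", SMART = "smart")`.
#' @param params a [ScoringParams-class]; `mergePfamSmart` is honoured after
#'   the mapping.
#' @return Named list of [ProteinArchitecture-class] objects.
#' @export
readInterproscanTsv <- function(path,
                                layerMap = c(Pfam = "pfam", SMART = "smart"),
                                params = ScoringParams()) {
  if (!file.exists(path)) stop("InterProScan TSV not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 11L)
    stop("InterProScan TSV needs >= 11 columns (length column missing?)")
  acc <- tab[[1L]]; len <- suppressWarnings(as.numeric(tab[[3L]]))
  analysis <- tab[[4L]]; sig <- tab[[5L]]
  start <- suppressWarnings(as.integer(tab[[7L]]))
  stopp <- suppressWarnings(as.integer(tab[[8L]]))
  score <- suppressWarnings(as.numeric(tab[[9L]]))
  if (anyNA(len)) stop("non-numeric protein length in InterProScan TSV")
  keep <- rep(TRUE, nrow(tab))
  badCoord <- is.na(start) | is.na(stopp)
  if (any(badCoord)) {
    warning(sum(badCoord), " row(s) with non-numeric start/stop rejected")
    keep <- keep & !badCoord
  }
  unmapped <- !(analysis %in% names(layerMap))
  if (any(unmapped & keep)) {
    warning("skipping unmapped analyses: ",
            paste(sort(unique(analysis[unmapped & keep])), collapse = ", "))
    keep <- keep & !unmapped
  }
  out <- list()
  for (id in unique(acc)) {
    sel <- keep & acc == id
    df <- if (any(sel)) {
      data.frame(layerId = unname(layerMap[analysis[sel]]),
                 typeId = paste0(tolower(analysis[sel]), ":", sig[sel]),
                 start = start[sel], end = stopp[sel],
                 evalue = score[sel], stringsAsFactors = FALSE)
    } else emptyFeatureTable()
    if (params@mergePfamSmart) df <- .mergePfamSmartLayers(df)
    out[[id]] <- ProteinArchitecture(id, len[match(id, acc)], df)
  }
  out
}

#' Read a feature-abundance count table
#'
#' Two-column TSV (`type_id`, `count`); counts are the number of instances
#' of each feature type in the reference proteome and drive the
#' abundance-based weighting schemes. A header line is tolerated (detected
#' by a non-numeric second field in the first row).
#'
#' @param path path to the TSV.
#' @return A [FeatureCounts-class] object.
#' @seealso [countFeatures()] to derive the table from a proteome annotation.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("count table must have two columns (type_id, count)")
  if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab[1L, 2L]))))
    tab <- tab[-1L, , drop = FALSE]            # header line
  if (!nrow(tab)) stop("count table is empty")
  ids <- tab[[1L]]
  cnt <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(cnt)) stop("non-numeric count in count table")
  if (any(cnt < 1)) stop("counts must be positive (got ", min(cnt), ")")
  if (anyDuplicated(ids))
    stop("duplicate type_id in count table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  FeatureCounts(setNames(cnt, ids))
}

#' Count feature-type instances across a proteome annotation
#'
#' Derives the abundance table used by the weighting schemes from a
#' collection of annotated proteins: `counts[t]` is the total number of
#' instances of type `t` across all architectures.
#'
#' @param architectures non-empty list of [ProteinArchitecture-class]
#'   objects.
#' @return A [FeatureCounts-class] object.
#' @export
countFeatures <- function(architectures) {
  if (length(architectures) == 0L)
    stop("cannot count features of an empty collection")
  types <- unlist(lapply(architectures, function(a) a@features$typeId),
                  use.names = FALSE)
  if (length(types) == 0L)
    stop("no feature instances in the collection; abundance weights would be undefined")
  tt <- table(types)
  FeatureCounts(setNames(as.integer(tt), names(tt)))
}
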