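## Seeded synthetic architecture generation: random multi-layered
## architectures, an ortholog-divergence perturbation model, and a
## deterministic worked-example fixture with redundant repeat annotations.

.syntheticLayers <- c("pfam_smart", "tmhmm", "seg", "coils", "flps")
.minInstanceWidth <- 5L

#' Generate a random protein architecture
#'
#' Instances are placed uniformly at random without constraint, so dense
#' annotations naturally produce overlapping, redundant layers. Layer names
#' follow the default feature space (`pfam_smart`, `tmhmm`, `seg`, `coils`,
#' `flps`, then `layer6`, ...); only the first layer carries e-values
#' (drawn log-uniformly down to 1e-30), mirroring pHMM-based annotations
#' versus e-value-free predictors. Output is a pure function of the seed.
#'
#' @param nLayers number of annotation layers.
#' @param nTypes number of feature types per layer.
#' @param nInstances number of instances per layer (0 gives an empty
#'   architecture).
#' @param length protein length in residues (must fit an instance of
#'   minimal width 5 when `nInstances > 0`).
#' @param seed RNG seed.
#' @param proteinId identifier of the generated protein.
#' @return A [ProteinArchitecture-class].
#' @examples
#' randomArchitecture(nLayers = 2, nTypes = 3, nInstances = 4, seed = 42)
#' @export
randomArchitecture <- function(nLayers = 2L, nTypes = 3L, nInstances = 4L,
                               length = 300L, seed,
                               proteinId = paste0("synth", seed)) {
  nLayers <- as.integer(nLayers); nTypes <- as.integer(nTypes)
  nInstances <- as.integer(nInstances); length <- as.integer(length)
  stopifnot(nLayers >= 1L, nTypes >= 1L, nInstances >= 0L, length >= 1L)
  if (nInstances > 0L && length < .minInstanceWidth)
    stop("protein of length ", length, " cannot fit an instance (minimum width ",
         .minInstanceWidth, ")")
  layers <- c(.syntheticLayers,
              paste0("layer", seq_len(max(0L, nLayers - 5L)) + 5L))[seq_len(nLayers)]
  withSeed(seed, {
    rows <- lapply(seq_along(layers), function(li) {
      layer <- layers[li]
      if (nInstances == 0L) return(NULL)
      types <- paste0(layer, ":T", sample.int(nTypes, nInstances, replace = TRUE))
      maxW <- max(.minInstanceWidth, min(length, length %/% 3L))
      wid <- sample(seq.int(.minInstanceWidth, maxW), nInstances, replace = TRUE)
      start <- vapply(wid, function(w) sample.int(length - w + 1L, 1L), integer(1L))
      ev <- if (li == 1L) 10^-runif(nInstances, 0, 30) else NA_real_
      data.frame(layerId = layer, typeId = types, start = start,
                 end = start + wid - 1L, evalue = ev, stringsAsFactors = FALSE)
    })
    ProteinArchitecture(proteinId, length, do.call(rbind, rows))
  })
}

#' Perturb an architecture with a seeded stochastic edit model
#'
#' Applies, in order: feature-type loss (probability `pLoss` per type),
#' instance duplication (`pDup` per instance, the copy placed at a random
#' valid position), positional shift (midpoint moved by a normal deviate
#' with SD `shiftSd * length`, width preserved, clipped to the protein),
#' and redundant decoy annotation (`pRedundant` per instance: an
#' overlapping same-layer copy under a fresh `decoy:` type id, jittered by
#' at most 2 residues so it always conflicts at `maxOverlap = 0`). With all
#' probabilities and `shiftSd` zero the input is returned unchanged. The
#' result is a pure function of `(arch, spec)`.
#'
#' @param arch a [ProteinArchitecture-class].
#' @param spec a [PerturbationSpec-class].
#' @return The perturbed [ProteinArchitecture-class].
#' @export
perturbArchitecture <- function(arch, spec) {
  stopifnot(is(arch, "ProteinArchitecture"), is(spec, "PerturbationSpec"))
  len <- arch@proteinLength
  withSeed(spec@seed, {
    df <- arch@features
    # type loss
    types <- unique(df$typeId)
    drop <- types[runif(length(types)) < spec@pLoss]
    df <- df[!(df$typeId %in% drop), , drop = FALSE]
    # duplication
    if (nrow(df)) {
      dup <- which(runif(nrow(df)) < spec@pDup)
      if (length(dup)) {
        copies <- df[dup, , drop = FALSE]
        w <- copies$end - copies$start + 1L
        ok <- w <= len
        copies <- copies[ok, , drop = FALSE]; w <- w[ok]
        if (nrow(copies)) {
          copies$start <- vapply(w, function(wi)
            sample.int(len - wi + 1L, 1L), integer(1L))
          copies$end <- copies$start + w - 1L
          df <- rbind(df, copies)
        }
      }
    }
    # positional shift, width preserved
    if (nrow(df)) {
      shift <- round(rnorm(nrow(df), 0, spec@shiftSd * len))
      w <- df$end - df$start + 1L
      df$start <- pmin(pmax(df$start + as.integer(shift), 1L), len - w + 1L)
      df$end <- df$start + w - 1L
    }
    # redundant decoys
    if (nrow(df)) {
      red <- which(runif(nrow(df)) < spec@pRedundant)
      if (length(red)) {
        decoys <- df[red, , drop = FALSE]
        w <- decoys$end - decoys$start + 1L
        jitter <- sample(-2:2, nrow(decoys), replace = TRUE)
        decoys$start <- pmin(pmax(decoys$start + jitter, 1L), len - w + 1L)
        decoys$end <- decoys$start + w - 1L
        decoys$typeId <- paste0("decoy:D", seq_along(red))
        decoys$evalue <- ifelse(is.na(decoys$evalue), NA_real_,
                                decoys$evalue * 10)
        df <- rbind(df, decoys)
      }
    }
    ProteinArchitecture(arch@proteinId, len, df)
  })
}

#' Deterministic redundant-repeat worked example
#'
#' A structural mimic of a classic ortholog pair whose repeat region
#' (TPR-like) is annotated redundantly by several alternative feature
#' types: the reference carries five mutually overlapping annotations per
#' repeat unit, of which only one type also occurs in the target; both
#' proteins share a C-terminal domain and an N-terminal low-complexity
#' segment. The e-values are arranged so that e-value minimization picks
#' the "wrong" type in the first repeat unit. Consequently the three
#' scoring strategies order as
#' `unresolved < e-value resolution < exhaustive score maximization`,
#' i.e. leaving overlaps unresolved dilutes the score and the e-value
#' baseline misses the optimal resolution.
#'
#' @return Named list with elements `ref` and `tgt`
#'   ([ProteinArchitecture-class] objects); deterministic (no RNG).
#' @examples
#' fx <- figure1Fixture()
#' fasValue(exhaustiveSearch(fx$ref, fx$tgt))
#' @export
figure1Fixture <- function() {
  slots <- list(c(60L, 100L), c(110L, 150L), c(160L, 200L))
  tprTypes <- c("pfam:TPR_1", "pfam:TPR_2", "pfam:TPR_7", "pfam:TPR_11",
                "smart:TPR")
  # e-values per slot x type: TPR_1 wins slot 1, TPR_2 wins slots 2 and 3
  ev <- rbind(c(1e-12, 1e-04, 1e-06, 1e-07, 1e-08),
              c(1e-08, 1e-11, 1e-06, 1e-07, 1e-05),
              c(1e-07, 1e-10, 1e-06, 1e-08, 1e-05))
  refRows <- do.call(rbind, lapply(seq_along(slots), function(s) {
    data.frame(layerId = "pfam_smart", typeId = tprTypes,
               start = slots[[s]][1L], end = slots[[s]][2L],
               evalue = ev[s, ], stringsAsFactors = FALSE)
  }))
  refRows <- rbind(refRows,
                   data.frame(layerId = c("pfam_smart", "seg"),
                              typeId = c("pfam:Pro_isomerase", "seg:low_complexity"),
                              start = c(320L, 10L), end = c(410L, 40L),
                              evalue = c(1e-40, NA), stringsAsFactors = FALSE))
  ref <- ProteinArchitecture("PPID_ref", 420L, refRows)
  tgtRows <- data.frame(
    layerId = c(rep("pfam_smart", 4L), "seg"),
    typeId = c(rep("pfam:TPR_2", 3L), "pfam:Pro_isomerase", "seg:low_complexity"),
    start = c(70L, 120L, 170L, 320L, 12L),
    end = c(110L, 160L, 210L, 410L, 42L),
    evalue = c(1e-09, 1e-09, 1e-09, 1e-38, NA), stringsAsFactors = FALSE)
  tgt <- ProteinArchitecture("PPID_tgt", 420L, tgtRows)
  list(ref = ref, tgt = tgt)
}
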