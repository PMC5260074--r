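#' @include AllClasses.R chemistry.R
NULL

## DNA target construction for the three design approaches.

.MODULAR_FLANK_GTT <- "GTT"
.MODULAR_FLANK_TAT <- "TAT"
.SYNERGISTIC_FLANK <- "TATGTTTAT"

#' Build a 9-bp modular DNA target
#'
#' Substitutes a 3-bp sub-site into the finger-specific 9-nt template:
#' `NNN-GTT-TAT` for finger 1, `TAT-NNN-TAT` for finger 2 and
#' `TAT-GTT-NNN` for finger 3. The two fixed sub-sites are the
#' negative-binder control sequence; only the designated window varies.
#'
#' @param triplet 3-letter ACGT string (primary strand, 5'->3').
#' @param fingerSlot integer 1, 2 or 3: which finger's sub-site the triplet
#'   occupies.
#' @return a [DnaTarget] of mode `"modular"`.
#' @examples
#' targetSequence(makeModularTarget("GCA", 1))  # "GCAGTTTAT"
#' targetSequence(makeModularTarget("GCA", 2))  # "TATGCATAT"
#' @export
makeModularTarget <- function(triplet, fingerSlot) {
  triplet <- .checkDnaString(triplet, "triplet")
  if (nchar(triplet) != 3L)
    stop("triplet must have exactly 3 bases", call. = FALSE)
  if (!(length(fingerSlot) == 1L && fingerSlot %in% 1:3))
    stop("fingerSlot must be 1, 2 or 3", call. = FALSE)
  seq <- switch(as.integer(fingerSlot),
    paste0(triplet, .MODULAR_FLANK_GTT, .MODULAR_FLANK_TAT),
    paste0(.MODULAR_FLANK_TAT, triplet, .MODULAR_FLANK_TAT),
    paste0(.MODULAR_FLANK_TAT, .MODULAR_FLANK_GTT, triplet))
  new("DnaTarget", mode = "modular", fingerSlot = as.integer(fingerSlot),
      triplet = triplet, sequence = seq,
      complement = reverseComplement(seq))
}

#' Build a 27-bp synergistic DNA target
#'
#' The whole-protein binding site: the 3-bp sub-site repeated three times
#' (one copy per finger), flanked on both sides by the fixed non-binding
#' sequence `TATGTTTAT`.
#'
#' @param triplet 3-letter ACGT string. The classic restricted design space
#'   uses GNN triplets, but any ACGT triplet is accepted here; restriction
#'   is applied by [enumerateTargets].
#' @return a [DnaTarget] of mode `"synergistic"` (27 nt).
#' @examples
#' targetSequence(makeSynergisticTarget("GGG"))
#' @export
makeSynergisticTarget <- function(triplet) {
  triplet <- .checkDnaString(triplet, "triplet")
  if (nchar(triplet) != 3L)
    stop("triplet must have exactly 3 bases", call. = FALSE)
  seq <- paste0(.SYNERGISTIC_FLANK, strrep(triplet, 3L), .SYNERGISTIC_FLANK)
  new("DnaTarget", mode = "synergistic", fingerSlot = NA_integer_,
      triplet = triplet, sequence = seq,
      complement = reverseComplement(seq))
}

#' All triplets under an alphabet restriction
#'
#' @param restriction `"NNN"` (all 64) or `"GNN"` (the 16 guanine-leading
#'   triplets).
#' @return character vector of triplets in lexicographic order.
#' @export
enumerateTriplets <- function(restriction = c("NNN", "GNN")) {
  restriction <- match.arg(restriction)
  b <- c("A", "C", "G", "T")
  first <- if (restriction == "GNN") "G" else b
  g <- expand.grid(p3 = b, p2 = b, p1 = first, stringsAsFactors = FALSE)
  trip <- sort(paste0(g$p1, g$p2, g$p3))
  trip
}

#' Enumerate DNA targets for a design run
#'
#' Modular mode yields one target per (triplet, finger slot); synergistic
#' mode one 27-bp target per triplet. Order is lexicographic over (triplet,
#' finger slot) so batch outputs are reproducible.
#'
#' @param mode `"modular"` or `"synergistic"`.
#' @param restriction `"NNN"` (64 triplets) or `"GNN"` (16).
#' @return list of [DnaTarget] objects; 192 for (modular, NNN), 16 for
#'   (synergistic, GNN).
#' @export
enumerateTargets <- function(mode = c("modular", "synergistic"),
                             restriction = c("NNN", "GNN")) {
  mode <- match.arg(mode)
  restriction <- match.arg(restriction)
  triplets <- enumerateTriplets(restriction)
  if (mode == "modular") {
    out <- vector("list", length(triplets) * 3L)
    i <- 0L
    for (trip in triplets) for (slot in 1:3) {
      i <- i + 1L
      out[[i]] <- makeModularTarget(trip, slot)
    }
    out
  } else {
    lapply(triplets, makeSynergisticTarget)
  }
}

#' Target identifier string
#' @param target a [DnaTarget].
#' @return e.g. `"modular_2_GCA"` or `"synergistic_all_GGG"`.
#' @export
targetId <- function(target) {
  stopifnot(is(target, "DnaTarget"))
  slot_txt <- if (is.na(target@fingerSlot)) "all" else target@fingerSlot
  sprintf("%s_%s_%s", target@mode, slot_txt, target@triplet)
}

#' Export targets as FASTA
#'
#' One record per target, header `<mode>_<slot>_<triplet>`.
#'
#' @param targets list of [DnaTarget] objects.
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
writeTargetsFasta <- function(targets, path) {
  stopifnot(length(targets) > 0L)
  seqs <- Biostrings::DNAStringSet(vapply(targets, targetSequence, character(1)))
  names(seqs) <- vapply(targets, targetId, character(1))
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}
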