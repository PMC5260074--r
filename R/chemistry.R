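## Residue dictionaries, element typing and the hydrogen-bond chemistry
## table (donor/acceptor roles for the 20 amino acids + 4 DNA bases).

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V")
names(.AA1) <- .AA3
.AA3_FROM_1 <- setNames(.AA3, .AA1)

## DNA residue names; both modern (DA) and legacy (A) dialects accepted.
.DNA_CANON <- c(DA = "DA", DG = "DG", DC = "DC", DT = "DT",
                A = "DA", G = "DG", C = "DC", T = "DT")

.BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT")
.DNA_BACKBONE <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                   "O3'", "C2'", "C1'")

## Positions of characters outside ACGT (integer(0) if clean).
.invalidBasePositions <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  which(!ch %in% c("A", "C", "G", "T"))
}

.checkDnaString <- function(seq, what = "sequence") {
  bad <- .invalidBasePositions(seq)
  if (length(bad))
    stop(sprintf("invalid base '%s' at position %d of %s",
                 substr(seq, bad[1L], bad[1L]), bad[1L], what), call. = FALSE)
  toupper(seq)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper over Biostrings for plain-character convenience.
#'
#' @param seq ACGT string (5'->3').
#' @return reverse-complement string (5'->3').
#' @export
reverseComplement <- function(seq) {
  seq <- .checkDnaString(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Element from a PDB atom name: first alphabetic character (works for all
## protein/nucleotide atom names in scope; two-letter metals not expected).
.elementFromName <- function(name) {
  el <- toupper(substr(gsub("^[^A-Za-z]*", "", name), 1L, 1L))
  el[!el %in% c("C", "N", "O", "S", "P", "H")] <- "X"
  el
}

## Molecule kind from a residue name.
.kindFromResname <- function(resname) {
  kind <- rep("other", length(resname))
  kind[resname %in% .AA3] <- "protein"
  kind[resname %in% names(.DNA_CANON)] <- "nucleotide"
  kind
}

## Canonical residue name (DNA dialects normalized).
.canonResname <- function(resname) {
  hit <- resname %in% names(.DNA_CANON)
  resname[hit] <- .DNA_CANON[resname[hit]]
  resname
}

## ---- donor/acceptor chemistry table ---------------------------------------
## One row per polar (N/O/S) atom of the 24 standard residues. ctx1/ctx2 are
## the heavy-atom neighbours used to place idealized polar hydrogens on sp2
## donors; rotatable donors (hydroxyl, thiol, ammonium) get theta = 0 by the
## energy-maximizing convention.

.daRow <- function(res, atom, role, maxH = 1L, rot = FALSE,
                   bb = FALSE, ctx1 = NA, ctx2 = NA, nnbr = 0L) {
  data.frame(resname = res, atom = atom, role = role,
             max_h = as.integer(maxH), rotatable = rot, backbone = bb,
             ctx1 = ctx1, ctx2 = ctx2, nnbr = as.integer(nnbr),
             stringsAsFactors = FALSE)
}

.buildDonorAcceptorTable <- function() {
  rows <- list(
    ## protein side chains
    .daRow("ARG", "NE",  "donor", 1L, FALSE, FALSE, "CD", "CZ", 2L),
    .daRow("ARG", "NH1", "donor", 2L, FALSE, FALSE, "CZ", "NE", 1L),
    .daRow("ARG", "NH2", "donor", 2L, FALSE, FALSE, "CZ", "NE", 1L),
    .daRow("ASN", "OD1", "acceptor"),
    .daRow("ASN", "ND2", "donor", 2L, FALSE, FALSE, "CG", "OD1", 1L),
    .daRow("ASP", "OD1", "acceptor"),
    .daRow("ASP", "OD2", "acceptor"),
    .daRow("CYS", "SG",  "both", 1L, TRUE),
    .daRow("GLN", "OE1", "acceptor"),
    .daRow("GLN", "NE2", "donor", 2L, FALSE, FALSE, "CD", "OE1", 1L),
    .daRow("GLU", "OE1", "acceptor"),
    .daRow("GLU", "OE2", "acceptor"),
    .daRow("HIS", "ND1", "both", 1L, FALSE, FALSE, "CG", "CE1", 2L),
    .daRow("HIS", "NE2", "both", 1L, FALSE, FALSE, "CD2", "CE1", 2L),
    .daRow("LYS", "NZ",  "donor", 3L, TRUE),
    .daRow("MET", "SD",  "acceptor"),
    .daRow("SER", "OG",  "both", 1L, TRUE),
    .daRow("THR", "OG1", "both", 1L, TRUE),
    .daRow("TRP", "NE1", "donor", 1L, FALSE, FALSE, "CD1", "CE2", 2L),
    .daRow("TYR", "OH",  "both", 1L, TRUE),
    ## DNA base edges
    .daRow("DA", "N1", "acceptor"),
    .daRow("DA", "N3", "acceptor"),
    .daRow("DA", "N7", "acceptor"),
    .daRow("DA", "N6", "donor", 2L, FALSE, FALSE, "C6", "N1", 1L),
    .daRow("DG", "N1", "donor", 1L, FALSE, FALSE, "C2", "C6", 2L),
    .daRow("DG", "N2", "donor", 2L, FALSE, FALSE, "C2", "N1", 1L),
    .daRow("DG", "N3", "acceptor"),
    .daRow("DG", "N7", "acceptor"),
    .daRow("DG", "O6", "acceptor"),
    .daRow("DC", "O2", "acceptor"),
    .daRow("DC", "N3", "acceptor"),
    .daRow("DC", "N4", "donor", 2L, FALSE, FALSE, "C4", "N3", 1L),
    .daRow("DT", "N3", "donor", 1L, FALSE, FALSE, "C2", "C4", 2L),
    .daRow("DT", "O2", "acceptor"),
    .daRow("DT", "O4", "acceptor"),
    ## glycosidic ring nitrogens: fully substituted, no H, lone pair in
    ## the ring plane is taken by the sugar bond - never donors/acceptors
    .daRow("DA", "N9", "none", 0L),
    .daRow("DG", "N9", "none", 0L),
    .daRow("DC", "N1", "none", 0L),
    .daRow("DT", "N1", "none", 0L))
  ## protein main chain (classified, excluded from scoring by default)
  for (res in .AA3) {
    rows[[length(rows) + 1L]] <-
      if (res == "PRO") .daRow(res, "N", "none", 0L, FALSE, TRUE)
      else .daRow(res, "N", "donor", 1L, FALSE, TRUE, "CA", NA, 1L)
    rows[[length(rows) + 1L]] <- .daRow(res, "O", "acceptor", 0L, FALSE, TRUE)
    rows[[length(rows) + 1L]] <- .daRow(res, "OXT", "acceptor", 0L, FALSE, TRUE)
  }
  ## DNA sugar-phosphate oxygens (backbone, excluded by default)
  for (res in c("DA", "DG", "DC", "DT")) {
    for (at in c("OP1", "OP2", "O3'", "O4'", "O5'"))
      rows[[length(rows) + 1L]] <- .daRow(res, at, "acceptor", 0L, FALSE, TRUE)
  }
  do.call(rbind, rows)
}

.DA_TABLE <- .buildDonorAcceptorTable()

#' Donor/acceptor chemistry table
#'
#' The fixed chemistry table assigning hydrogen-bond roles (donor, acceptor,
#' both, none) to every polar N/O/S atom of the 20 standard amino acids and
#' the 4 DNA bases. Carbon and phosphorus atoms never appear: only N, O and
#' S can take part in a scored hydrogen bond. Backbone rows (protein
#' main-chain N/O, DNA sugar-phosphate oxygens) are flagged and excluded
#' from interface scoring unless requested.
#'
#' @return data.frame with columns `resname`, `atom`, `role`, `max_h`,
#'   `rotatable`, `backbone`, `ctx1`, `ctx2`.
#' @export
donorAcceptorTable <- function() .DA_TABLE
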