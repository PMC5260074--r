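#' @include chemistry.R
NULL

.ATOM_COLS <- c("serial", "name", "resname", "chain", "resno",
                "x", "y", "z", "element", "kind", "backbone")

#' Molecular structure container
#'
#' Holds the atoms of a (possibly multi-chain) protein-DNA structure as a
#' flat table. Each row is one atom with PDB-style naming, Cartesian
#' coordinates in Angstrom, a chemical element assignment and a
#' molecule-kind annotation (`"protein"`, `"nucleotide"` or `"other"`)
#' derived from the residue name.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`, `element`, `kind`, `backbone`.
#'
#' @seealso [readPDB], [writePDB], [buildBDNA]
#' @exportClass StructureModel
setClass("StructureModel", representation(atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  missing_cols <- setdiff(.ATOM_COLS, names(a))
  if (length(missing_cols))
    return(paste("missing atom columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite atom coordinates")
    key <- paste(a$chain, a$resno, a$name)
    if (anyDuplicated(key))
      return(paste("duplicate (chain, residue, atom) entries, e.g.",
                   key[duplicated(key)][1L]))
  }
  TRUE
})

#' DNA target sequence for one design run
#'
#' A DNA target in either the modular (9-nt, one finger's triplet embedded
#' in a fixed template) or synergistic (27-nt, triplet repeated three times
#' between fixed flanks) layout. The primary strand is the printed 5'->3'
#' string; the reverse-complement second strand is carried alongside.
#'
#' @slot mode `"modular"` or `"synergistic"`.
#' @slot fingerSlot integer; 1, 2 or 3 for modular targets, `NA` for
#'   synergistic ones (all fingers).
#' @slot triplet 3-letter ACGT string, the variable sub-site.
#' @slot sequence full primary-strand sequence (9 or 27 nt).
#' @slot complement reverse complement of `sequence`.
#'
#' @seealso [makeModularTarget], [makeSynergisticTarget], [enumerateTargets]
#' @exportClass DnaTarget
setClass("DnaTarget", representation(
  mode = "character", fingerSlot = "integer", triplet = "character",
  sequence = "character", complement = "character"))

setValidity("DnaTarget", function(object) {
  if (!object@mode %in% c("modular", "synergistic"))
    return("mode must be 'modular' or 'synergistic'")
  if (nchar(object@triplet) != 3L)
    return("triplet must have exactly 3 bases")
  bad <- .invalidBasePositions(object@triplet)
  if (length(bad))
    return(sprintf("invalid base at triplet position %d", bad[1L]))
  want <- if (object@mode == "modular") 9L else 27L
  if (nchar(object@sequence) != want)
    return(sprintf("%s sequence must be %d nt", object@mode, want))
  if (object@mode == "modular" && !(object@fingerSlot %in% 1:3))
    return("fingerSlot must be 1, 2 or 3 for modular targets")
  if (object@complement != reverseComplement(object@sequence))
    return("complement slot is not the reverse complement of sequence")
  TRUE
})

#' Candidate recognition helix
#'
#' One zinc-finger recognition helix on the Zif-268-style scaffold: a
#' 7-position stretch (-1, +1 ... +6 relative to the helix start) whose key
#' specificity residues sit at -1, +3 and +6 while the scaffold positions
#' +1, +2, +4, +5 stay fixed (default S, G, L, T).
#'
#' @slot fingerIndex which finger (1-3) the helix is intended for.
#' @slot residues named character vector of one-letter residues for
#'   positions `"-1","1","2","3","4","5","6"`.
#'
#' @seealso [enumerateHelices], [shortCode], [longCode]
#' @exportClass RecognitionHelix
setClass("RecognitionHelix", representation(
  fingerIndex = "integer", residues = "character"))

.HELIX_POSITIONS <- c("-1", "1", "2", "3", "4", "5", "6")

setValidity("RecognitionHelix", function(object) {
  if (!identical(names(object@residues), .HELIX_POSITIONS))
    return("residues must be named -1,1,2,3,4,5,6 in order")
  if (!all(object@residues %in% .AA1))
    return("residues must be one-letter codes of the 20 standard amino acids")
  if (!(object@fingerIndex %in% 1:3))
    return("fingerIndex must be 1, 2 or 3")
  TRUE
})

#' Per-position amino-acid pools for helix enumeration
#'
#' The allowed one-letter residue sets at the key helix positions -1, +3 and
#' +6 (optionally +2). The Cartesian product of the sets is the candidate
#' helix space.
#'
#' @slot pools named list of character vectors, names among
#'   `"-1"`, `"2"`, `"3"`, `"6"`.
#'
#' @seealso [poolFromConfig], [enumerateHelices]
#' @exportClass AminoAcidPool
setClass("AminoAcidPool", representation(pools = "list"))

setValidity("AminoAcidPool", function(object) {
  p <- object@pools
  if (!all(names(p) %in% c("-1", "2", "3", "6")))
    return("pool positions must be among -1, 2, 3, 6")
  if (!all(c("-1", "3", "6") %in% names(p)))
    return("pools for positions -1, 3 and 6 are required")
  for (nm in names(p)) {
    if (!length(p[[nm]]))
      return(sprintf("empty amino-acid pool at position %s", nm))
    if (!all(p[[nm]] %in% .AA1))
      return(sprintf("pool at position %s contains non-standard residues", nm))
    if (anyDuplicated(p[[nm]]))
      return(sprintf("pool at position %s contains duplicates", nm))
  }
  TRUE
})

#' Hydrogen-bond energy parameters
#'
#' Parameters of the interfacial hydrogen-bond potential: per element-pair
#' class (N-N, N-O, O-O) the well depth epsilon (kcal/mol) and optimum
#' donor-acceptor distance d' (Angstrom), plus the heavy-atom screening
#' cutoff. Defaults are the AMBER99-style values: 2.0/3.2 (N-N), 2.8/3.0
#' (N-O), 4.0/2.8 (O-O), cutoff 3.5 Angstrom.
#'
#' @slot epsilon named numeric, kcal/mol per class.
#' @slot dOpt named numeric, Angstrom per class.
#' @slot cutoff heavy-atom donor-acceptor screening distance, Angstrom.
#' @slot thetaMax maximum deviation-from-linearity (degrees) for a counted
#'   bond; geometries beyond it are rejected rather than scored positive.
#' @slot sulfurAs element whose parameter rows sulfur borrows (`"O"` or
#'   `"N"`); the parameter table itself has no sulfur row.
#' @slot includeBackbone logical; score main-chain protein N/O and DNA
#'   sugar-phosphate oxygens as donors/acceptors (default `FALSE`: side
#'   chains and base edges only).
#' @slot hMode `"idealized"` (polar hydrogens placed by hybridization rules,
#'   rotatable donors oriented toward the acceptor) or `"strict"` (explicit
#'   hydrogen atoms required in the model).
#'
#' @seealso [hbondEnergy], [scoreComplex]
#' @exportClass HBondParams
setClass("HBondParams", representation(
  epsilon = "numeric", dOpt = "numeric", cutoff = "numeric",
  thetaMax = "numeric", sulfurAs = "character",
  includeBackbone = "logical", hMode = "character"))

setValidity("HBondParams", function(object) {
  cls <- c("N-N", "N-O", "O-O")
  if (!identical(names(object@epsilon), cls) ||
      !identical(names(object@dOpt), cls))
    return("epsilon and dOpt must be named N-N, N-O, O-O")
  if (any(!is.finite(object@epsilon)) || any(object@epsilon <= 0))
    return("epsilon values must be finite and positive")
  if (any(!is.finite(object@dOpt)) || any(object@dOpt <= 0))
    return("dOpt values must be finite and positive")
  if (!is.finite(object@cutoff) || object@cutoff <= 0)
    return("cutoff must be positive")
  if (!object@sulfurAs %in% c("O", "N"))
    return("sulfurAs must be 'O' or 'N'")
  if (!object@hMode %in% c("idealized", "strict"))
    return("hMode must be 'idealized' or 'strict'")
  TRUE
})

#' Score for one helix/target complex
#'
#' The interfacial hydrogen-bond energy of one scored complex: the resolved
#' bond list, the signed total (negative = favorable) and the absolute-value
#' score used for ranking.
#'
#' @slot helixId identifier of the scored helix (its 7-letter code).
#' @slot triplet the DNA sub-site (or 9-bp repeated-triplet target).
#' @slot finger finger slot (1-3), or `NA` for whole-complex scores.
#' @slot bonds data.frame of resolved hydrogen bonds (donor, acceptor,
#'   distance, theta, class, energy).
#' @slot totalEnergy signed sum of bond energies, kcal/mol.
#' @slot score absolute value of `totalEnergy`, kcal/mol.
#'
#' @seealso [scoreComplex], [rankRecords]
#' @exportClass ScoreRecord
setClass("ScoreRecord", representation(
  helixId = "character", triplet = "character", finger = "integer",
  bonds = "data.frame", totalEnergy = "numeric", score = "numeric"))

setValidity("ScoreRecord", function(object) {
  tot <- if (nrow(object@bonds)) sum(object@bonds$energy) else 0
  if (abs(object@totalEnergy - tot) > 1e-9)
    return("totalEnergy does not equal the sum of bond energies")
  if (abs(object@score - abs(object@totalEnergy)) > 1e-12)
    return("score must be |totalEnergy|")
  TRUE
})

#' Ranked helices for one target key
#'
#' Ordered score records for one (triplet, finger) key (modular) or one
#' whole target (synergistic): descending by absolute score, ties broken by
#' more-negative signed energy then helix code, ranks 1..n without gaps.
#'
#' @slot key target key, e.g. `"GCA/F1"` or a 9-bp sequence.
#' @slot records data.frame with columns `rank`, `helix`, `short_code`,
#'   `triplet`, `finger`, `total_energy`, `score`, `n_bonds`.
#'
#' @seealso [rankRecords], [runModular], [runSynergistic]
#' @exportClass RankingTable
setClass("RankingTable", representation(key = "character", records = "data.frame"))

setValidity("RankingTable", function(object) {
  r <- object@records
  if (!nrow(r)) return(TRUE)
  if (!identical(r$rank, seq_len(nrow(r))))
    return("ranks must be 1..n without gaps")
  if (is.unsorted(-r$score))
    return("records must be ordered by descending score")
  TRUE
})

#' Result of threading a helix onto a template
#'
#' @slot model the mutated [StructureModel]; backbone atoms identical to the
#'   input model's.
#' @slot sites data.frame of mutated sites (chain, resno, old and new
#'   residue, chosen rotamer index, clash count).
#'
#' @seealso [applyHelix], [placeSidechain]
#' @exportClass MutationResult
setClass("MutationResult", representation(model = "StructureModel",
                                          sites = "data.frame"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel: %d atoms, %d chains (%s)\n", nrow(a),
              length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ",")))
  if (nrow(a)) {
    k <- table(a$kind)
    cat("  kinds:", paste(sprintf("%s=%d", names(k), k), collapse = " "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "DnaTarget", function(object) {
  slot_txt <- if (is.na(object@fingerSlot)) "all fingers"
              else sprintf("finger %d", object@fingerSlot)
  cat(sprintf("DnaTarget (%s, %s): 5'-%s-3'\n",
              object@mode, slot_txt, object@sequence))
  invisible(NULL)
})

setMethod("show", "RecognitionHelix", function(object) {
  cat(sprintf("RecognitionHelix F%d: %s (key %s at -1/+3/+6)\n",
              object@fingerIndex, longCode(object), shortCode(object)))
  invisible(NULL)
})

setMethod("show", "AminoAcidPool", function(object) {
  cat("AminoAcidPool:\n")
  for (nm in names(object@pools))
    cat(sprintf("  position %-2s: {%s} (%d)\n", nm,
                paste(object@pools[[nm]], collapse = ","),
                length(object@pools[[nm]])))
  invisible(NULL)
})

setMethod("show", "HBondParams", function(object) {
  cat("HBondParams (10-12 potential x cos^4 theta):\n")
  for (cl in names(object@epsilon))
    cat(sprintf("  %s: epsilon = %.1f kcal/mol, d' = %.1f A\n",
                cl, object@epsilon[[cl]], object@dOpt[[cl]]))
  cat(sprintf("  cutoff %.2f A, theta <= %.0f deg, S scored as %s, %s H\n",
              object@cutoff, object@thetaMax, object@sulfurAs, object@hMode))
  invisible(NULL)
})

setMethod("show", "ScoreRecord", function(object) {
  cat(sprintf("ScoreRecord %s vs %s%s: %d bond(s), total %+.3f kcal/mol, score %.3f\n",
              object@helixId, object@triplet,
              if (is.na(object@finger)) "" else sprintf(" (F%d)", object@finger),
              nrow(object@bonds), object@totalEnergy, object@score))
  invisible(NULL)
})

setMethod("show", "RankingTable", function(object) {
  cat(sprintf("RankingTable [%s]: %d record(s)\n", object@key,
              nrow(object@records)))
  if (nrow(object@records))
    print(head(object@records, 5L), row.names = FALSE)
  invisible(NULL)
})

setMethod("show", "MutationResult", function(object) {
  cat(sprintf("MutationResult: %d site(s) mutated\n", nrow(object@sites)))
  if (nrow(object@sites)) print(object@sites, row.names = FALSE)
  invisible(NULL)
})
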