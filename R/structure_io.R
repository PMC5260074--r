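#' @include AllClasses.R chemistry.R
NULL

## PDB parsing into StructureModel, donor/acceptor classification and
## recognition-helix residue selection.

#' Read a PDB file into a StructureModel
#'
#' Parses ATOM/HETATM records through bio3d, types elements from atom
#' names, partitions chains into protein/nucleotide/other by residue-name
#' dictionary (both `DA`-style and legacy one-letter DNA residue names are
#' accepted) and resolves alternate locations to the highest-occupancy
#' copy. Water and other unknown residues are kept with
#' `kind = "other"` and a warning.
#'
#' @param path PDB file.
#' @return a [StructureModel].
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e)
                    stop(sprintf("failed to parse %s: %s", path,
                                 conditionMessage(e)), call. = FALSE))
  a <- pdb$atom
  if (!nrow(a)) stop(sprintf("no atoms in %s", path), call. = FALSE)
  occ <- ifelse(is.na(a$o), 1, a$o)
  ## alternate locations: keep the highest-occupancy copy per atom site
  key <- paste(a$chain, a$resno, a$resid, a$elety)
  keep <- rep(TRUE, nrow(a))
  for (dupkey in unique(key[duplicated(key)])) {
    idx <- which(key == dupkey)
    keep[idx] <- FALSE
    keep[idx[which.max(occ[idx])]] <- TRUE
  }
  a <- a[keep, , drop = FALSE]
  resname <- .canonResname(trimws(a$resid))
  name <- trimws(a$elety)
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  kind <- .kindFromResname(resname)
  if (any(kind == "other")) {
    unk <- unique(resname[kind == "other"])
    warning(sprintf("unknown residue name(s) %s: molecule kind set to 'other'",
                    paste(unk, collapse = ", ")), call. = FALSE)
  }
  df <- .makeAtomsDF(name, resname, chain, a$resno,
                     cbind(a$x, a$y, a$z))
  new("StructureModel", atoms = df)
}

#' Assign hydrogen-bond roles to atoms
#'
#' Looks atoms up in the fixed donor/acceptor chemistry table
#' ([donorAcceptorTable]). Only nitrogen, oxygen and sulfur atoms can act
#' as donors or acceptors; every carbon (and phosphorus) atom gets role
#' `"none"`. Polar atoms of known residues that are missing from the table
#' get role `"none"` with a warning.
#'
#' @param model a [StructureModel].
#' @param includeBackbone keep protein main-chain and DNA sugar-phosphate
#'   roles (default `FALSE`: they are classified but reported with role
#'   `"none"` so that only side-chain and base-edge atoms score).
#' @return the atom table with extra columns `role`, `max_h`, `rotatable`,
#'   `ctx1`, `ctx2`.
#' @export
classifyDonorAcceptor <- function(model, includeBackbone = FALSE) {
  a <- atoms(model)
  tab <- donorAcceptorTable()
  idx <- match(paste(a$resname, a$name), paste(tab$resname, tab$atom))
  role <- ifelse(is.na(idx), "none", tab$role[idx])
  max_h <- ifelse(is.na(idx), 0L, tab$max_h[idx])
  rotatable <- ifelse(is.na(idx), FALSE, tab$rotatable[idx])
  ctx1 <- ifelse(is.na(idx), NA, tab$ctx1[idx])
  ctx2 <- ifelse(is.na(idx), NA, tab$ctx2[idx])
  nnbr <- ifelse(is.na(idx), 0L, tab$nnbr[idx])
  is_bb <- ifelse(is.na(idx), FALSE, tab$backbone[idx])
  if (!includeBackbone) role[is_bb] <- "none"
  ## polar atom of a known residue without a table entry: warn once
  polar <- a$element %in% c("N", "O", "S") & a$kind != "other"
  orphan <- polar & is.na(idx)
  if (any(orphan)) {
    ex <- unique(paste(a$resname[orphan], a$name[orphan]))
    warning(sprintf("polar atom(s) without chemistry-table entry: %s (role 'none')",
                    paste(utils::head(ex, 5L), collapse = ", ")), call. = FALSE)
  }
  cbind(a, role = role, max_h = max_h, rotatable = rotatable,
        ctx1 = ctx1, ctx2 = ctx2, nnbr = nnbr, stringsAsFactors = FALSE)
}

## ---- recognition-helix position maps --------------------------------------

#' Default Zif-268-style position map
#'
#' Maps each finger's recognition-helix positions to residue numbers:
#' position +1 is the helix start, so position p (p in -1..6) resolves to
#' residue `helix_start + p - 1`. The shipped default follows the Zif-268
#' template numbering (helix starts 19, 47, 75 on chain A); it is plain
#' configuration and can be replaced for any other scaffold via
#' [readPositionMap].
#'
#' @return list with elements `chain` and `helix_start` (integer vector,
#'   one per finger).
#' @export
defaultPositionMap <- function() {
  list(chain = "A", helix_start = c(19L, 47L, 75L))
}

#' Read a position map from a YAML file
#'
#' The file must define `chain` and `helix_start` (one integer per finger).
#'
#' @param path YAML file.
#' @return position map list (see [defaultPositionMap]).
#' @export
readPositionMap <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chain) || is.null(cfg$helix_start))
    stop("position map must define 'chain' and 'helix_start'", call. = FALSE)
  list(chain = as.character(cfg$chain),
       helix_start = as.integer(cfg$helix_start))
}

#' Resolve helix positions to residue numbers
#'
#' @param positionMap a position map (see [defaultPositionMap]).
#' @param finger finger index (1-based).
#' @param positions integer helix positions, each in -1..6 (0 is not a
#'   helix position).
#' @return integer residue numbers.
#' @export
resolveHelixPositions <- function(positionMap, finger, positions) {
  if (finger < 1L || finger > length(positionMap$helix_start))
    stop(sprintf("finger %d not in position map", finger), call. = FALSE)
  if (any(positions < -1L | positions > 6L | positions == 0L))
    stop(sprintf("invalid helix position %d for finger %d",
                 positions[which(positions < -1L | positions > 6L |
                                 positions == 0L)][1L], finger),
         call. = FALSE)
  start <- positionMap$helix_start[finger]
  ## no position 0: -1 sits directly before the helix start (+1)
  as.integer(ifelse(positions >= 1L, start + positions - 1L,
                    start + positions))
}

#' Select recognition-helix and base residues at the interface
#'
#' Returns the protein residues at the configured key helix positions of
#' one finger together with the bases of that finger's 3-bp sub-site on the
#' primary DNA strand.
#'
#' @param model a protein-DNA complex [StructureModel].
#' @param positionMap position map (see [defaultPositionMap]).
#' @param finger finger index.
#' @param tripletResnos integer residue numbers of the sub-site bases on
#'   the primary DNA strand.
#' @param dnaChain DNA chain id holding the primary strand (default `"A"`
#'   when the protein sits on another chain; pass explicitly for multi-chain
#'   complexes).
#' @param keyPositions helix positions scored as the recognition helix
#'   (default -1, 2, 3, 6).
#' @return list with data.frames `helix` (protein atoms) and `bases`
#'   (nucleotide atoms).
#' @export
selectInterfaceResidues <- function(model, positionMap, finger,
                                    tripletResnos, dnaChain = "D",
                                    keyPositions = c(-1L, 2L, 3L, 6L)) {
  a <- atoms(model)
  resnos <- resolveHelixPositions(positionMap, finger, keyPositions)
  helix <- a[a$chain == positionMap$chain & a$resno %in% resnos &
             a$kind == "protein", , drop = FALSE]
  if (!nrow(helix))
    stop(sprintf("no protein atoms at positions {%s} of finger %d (chain %s)",
                 paste(keyPositions, collapse = ","), finger,
                 positionMap$chain), call. = FALSE)
  found <- sort(unique(helix$resno))
  missing <- setdiff(resnos, found)
  if (length(missing))
    stop(sprintf("finger %d: residue(s) %s outside chain %s",
                 finger, paste(missing, collapse = ","), positionMap$chain),
         call. = FALSE)
  bases <- a[a$chain == dnaChain & a$resno %in% tripletResnos &
             a$kind == "nucleotide", , drop = FALSE]
  if (!nrow(bases))
    stop(sprintf("no nucleotide atoms at residues {%s} of chain %s",
                 paste(tripletResnos, collapse = ","), dnaChain),
         call. = FALSE)
  list(helix = helix, bases = bases)
}
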