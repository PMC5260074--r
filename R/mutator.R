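#' @include geometry.R AllClasses.R
NULL

## Fixed-backbone side-chain threading. Side chains are rebuilt from ideal
## internal geometry (bond lengths/angles from standard small-molecule
## values) and the chi dihedrals of a rotamer drawn from an empirical
## library; the backbone (N, CA, C, O) is never touched.

.zfscoreCache <- new.env(parent = emptyenv())

## Number of chi dihedrals per residue (standard chemistry).
.N_CHI <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L,
            GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L,
            MET = 3L, PHE = 2L, PRO = 2L, SER = 1L, THR = 1L, TRP = 2L,
            TYR = 2L, VAL = 1L)

## Four-atom definitions of each chi, for recomputing dihedrals from
## coordinates (round-trip oracle of the builder).
.CHI_DEFS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  PRO = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1")))

## Side-chain construction tables: each atom placed by NeRF from
## (parent, aref, dref) with bond length r (A), angle a (deg) and a
## dihedral that is either chi number `chi` plus `dihe` offset, or the
## fixed value `dihe` when chi = 0. CB (from the backbone frame) is
## prepended for every non-Gly residue at build time.
.scRow <- function(name, parent, aref, dref, r, a, chi, dihe) {
  list(name = name, parent = parent, aref = aref, dref = dref,
       r = r, a = a, chi = chi, dihe = dihe)
}

.SC_TOPOLOGY <- list(
  ALA = list(),
  SER = list(.scRow("OG", "CB", "CA", "N", 1.42, 110.5, 1L, 0)),
  CYS = list(.scRow("SG", "CB", "CA", "N", 1.81, 114.0, 1L, 0)),
  THR = list(.scRow("OG1", "CB", "CA", "N", 1.43, 109.5, 1L, 0),
             .scRow("CG2", "CB", "CA", "N", 1.52, 110.5, 1L, -120)),
  VAL = list(.scRow("CG1", "CB", "CA", "N", 1.52, 110.5, 1L, 0),
             .scRow("CG2", "CB", "CA", "N", 1.52, 110.5, 1L, 120)),
  LEU = list(.scRow("CG", "CB", "CA", "N", 1.53, 116.3, 1L, 0),
             .scRow("CD1", "CG", "CB", "CA", 1.52, 110.7, 2L, 0),
             .scRow("CD2", "CG", "CB", "CA", 1.52, 110.7, 2L, 120)),
  ILE = list(.scRow("CG1", "CB", "CA", "N", 1.53, 110.4, 1L, 0),
             .scRow("CG2", "CB", "CA", "N", 1.52, 110.5, 1L, -120),
             .scRow("CD1", "CG1", "CB", "CA", 1.51, 113.9, 2L, 0)),
  MET = list(.scRow("CG", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
             .scRow("SD", "CG", "CB", "CA", 1.80, 112.7, 2L, 0),
             .scRow("CE", "SD", "CG", "CB", 1.79, 100.9, 3L, 0)),
  ASP = list(.scRow("CG", "CB", "CA", "N", 1.52, 112.6, 1L, 0),
             .scRow("OD1", "CG", "CB", "CA", 1.25, 118.4, 2L, 0),
             .scRow("OD2", "CG", "CB", "CA", 1.25, 118.4, 2L, 180)),
  ASN = list(.scRow("CG", "CB", "CA", "N", 1.52, 112.6, 1L, 0),
             .scRow("OD1", "CG", "CB", "CA", 1.23, 120.8, 2L, 0),
             .scRow("ND2", "CG", "CB", "CA", 1.33, 116.4, 2L, 180)),
  GLU = list(.scRow("CG", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
             .scRow("CD", "CG", "CB", "CA", 1.52, 112.6, 2L, 0),
             .scRow("OE1", "CD", "CG", "CB", 1.25, 118.4, 3L, 0),
             .scRow("OE2", "CD", "CG", "CB", 1.25, 118.4, 3L, 180)),
  GLN = list(.scRow("CG", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
             .scRow("CD", "CG", "CB", "CA", 1.52, 112.6, 2L, 0),
             .scRow("OE1", "CD", "CG", "CB", 1.23, 120.8, 3L, 0),
             .scRow("NE2", "CD", "CG", "CB", 1.33, 116.4, 3L, 180)),
  LYS = list(.scRow("CG", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
             .scRow("CD", "CG", "CB", "CA", 1.52, 111.3, 2L, 0),
             .scRow("CE", "CD", "CG", "CB", 1.52, 111.3, 3L, 0),
             .scRow("NZ", "CE", "CD", "CG", 1.49, 111.9, 4L, 0)),
  ARG = list(.scRow("CG", "CB", "CA", "N", 1.52, 114.1, 1L, 0),
             .scRow("CD", "CG", "CB", "CA", 1.52, 111.3, 2L, 0),
             .scRow("NE", "CD", "CG", "CB", 1.46, 112.0, 3L, 0),
             .scRow("CZ", "NE", "CD", "CG", 1.33, 124.2, 4L, 0),
             .scRow("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0L, 0),
             .scRow("NH2", "CZ", "NE", "CD", 1.33, 120.0, 0L, 180)),
  HIS = list(.scRow("CG", "CB", "CA", "N", 1.50, 113.8, 1L, 0),
             .scRow("ND1", "CG", "CB", "CA", 1.38, 122.7, 2L, 0),
             .scRow("CD2", "CG", "CB", "CA", 1.36, 129.7, 2L, 180),
             .scRow("CE1", "ND1", "CG", "CB", 1.32, 109.3, 0L, 180),
             .scRow("NE2", "CE1", "ND1", "CG", 1.32, 111.5, 0L, 0)),
  PHE = list(.scRow("CG", "CB", "CA", "N", 1.50, 113.8, 1L, 0),
             .scRow("CD1", "CG", "CB", "CA", 1.39, 120.8, 2L, 0),
             .scRow("CD2", "CG", "CB", "CA", 1.39, 120.8, 2L, 180),
             .scRow("CE1", "CD1", "CG", "CB", 1.39, 120.0, 0L, 180),
             .scRow("CE2", "CD2", "CG", "CB", 1.39, 120.0, 0L, 180),
             .scRow("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0L, 0)),
  TYR = list(.scRow("CG", "CB", "CA", "N", 1.50, 113.8, 1L, 0),
             .scRow("CD1", "CG", "CB", "CA", 1.39, 120.8, 2L, 0),
             .scRow("CD2", "CG", "CB", "CA", 1.39, 120.8, 2L, 180),
             .scRow("CE1", "CD1", "CG", "CB", 1.39, 120.0, 0L, 180),
             .scRow("CE2", "CD2", "CG", "CB", 1.39, 120.0, 0L, 180),
             .scRow("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0L, 0),
             .scRow("OH", "CZ", "CE1", "CD1", 1.38, 120.0, 0L, 180)),
  TRP = list(.scRow("CG", "CB", "CA", "N", 1.50, 113.8, 1L, 0),
             .scRow("CD1", "CG", "CB", "CA", 1.37, 127.0, 2L, 0),
             .scRow("CD2", "CG", "CB", "CA", 1.43, 126.6, 2L, 180),
             .scRow("NE1", "CD1", "CG", "CB", 1.38, 110.2, 0L, 180),
             .scRow("CE2", "CD2", "CG", "CB", 1.41, 107.2, 0L, 180),
             .scRow("CE3", "CD2", "CG", "CB", 1.40, 133.9, 0L, 0),
             .scRow("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, 0L, 180),
             .scRow("CZ3", "CE3", "CD2", "CG", 1.39, 118.7, 0L, 180),
             .scRow("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, 0L, 0)),
  PRO = list(.scRow("CG", "CB", "CA", "N", 1.49, 104.5, 1L, 0),
             .scRow("CD", "CG", "CB", "CA", 1.50, 106.1, 2L, 0)),
  GLY = list())

## ---- rotamer library ------------------------------------------------------

#' Read a rotamer library from TSV
#'
#' Flat table with columns `resname`, `chi1`..`chi4` (degrees, NA where a
#' residue has fewer dihedrals) and `frequency` (empirical prior). The chi
#' count of every row must match the residue's chemistry and frequencies
#' must sum to at most 1 per residue.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readRotamerLibrary <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("resname", "chi1", "chi2", "chi3", "chi4", "frequency")
  if (!all(need %in% names(lib)))
    stop("rotamer library must have columns resname, chi1..chi4, frequency",
         call. = FALSE)
  for (i in seq_len(nrow(lib))) {
    res <- lib$resname[i]
    if (!res %in% names(.N_CHI))
      stop(sprintf("unknown residue '%s' in rotamer library", res),
           call. = FALSE)
    nchi <- sum(!is.na(as.numeric(lib[i, c("chi1", "chi2", "chi3", "chi4")])))
    if (nchi != .N_CHI[[res]])
      stop(sprintf("rotamer row %d (%s): %d chi angles, expected %d",
                   i, res, nchi, .N_CHI[[res]]), call. = FALSE)
  }
  if (any(lib$frequency < 0 | lib$frequency > 1))
    stop("rotamer frequencies must lie in [0, 1]", call. = FALSE)
  sums <- tapply(lib$frequency, lib$resname, sum)
  if (any(sums > 1 + 1e-6))
    stop(sprintf("rotamer frequencies for %s sum to more than 1",
                 names(sums)[which(sums > 1 + 1e-6)][1L]), call. = FALSE)
  lib
}

#' Built-in minimal rotamer library
#'
#' A small library (1-4 common rotamers per residue, frequencies from the
#' usual empirical preferences) shipped with the package; sufficient for
#' threading and for tests. Replace with [readRotamerLibrary] for a full
#' library.
#'
#' @return rotamer data.frame.
#' @export
defaultRotamerLibrary <- function() {
  cached <- get0("rotamer_library", envir = .zfscoreCache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "rotamer_library.tsv", package = "zfscore")
  if (path == "") path <- file.path("inst", "extdata", "rotamer_library.tsv")
  lib <- readRotamerLibrary(path)
  assign("rotamer_library", lib, envir = .zfscoreCache)
  lib
}

.rotamerChis <- function(librow) {
  chis <- as.numeric(librow[1L, c("chi1", "chi2", "chi3", "chi4")])
  chis[!is.na(chis)]
}

## ---- side-chain placement -------------------------------------------------

.residueAtoms <- function(a, chain, resno) {
  which(a$chain == chain & a$resno == resno)
}

.getCoord <- function(a, idx, name) {
  j <- idx[a$name[idx] == name]
  if (!length(j)) return(NULL)
  as.numeric(a[j[1L], c("x", "y", "z")])
}

## Build side-chain coordinates for `res3` given backbone N/CA/C and chis.
## Returns named list of atom coordinate vectors (CB first).
.buildSidechain <- function(res3, N, CA, C, chis) {
  topo <- .SC_TOPOLOGY[[res3]]
  nchi <- .N_CHI[[res3]]
  if (length(chis) != nchi)
    stop(sprintf("%s needs %d chi angle(s), got %d", res3, nchi,
                 length(chis)), call. = FALSE)
  if (res3 == "GLY") return(list())
  coords <- list(N = N, CA = CA, C = C)
  coords[["CB"]] <- .placeAtom(C, N, CA, 1.53, 110.5, -122.6)
  for (row in topo) {
    dih <- if (row$chi > 0L) chis[row$chi] + row$dihe else row$dihe
    coords[[row$name]] <- .placeAtom(coords[[row$dref]], coords[[row$aref]],
                                     coords[[row$parent]], row$r, row$a, dih)
  }
  coords[setdiff(names(coords), c("N", "CA", "C"))]
}

#' Recompute chi dihedrals from coordinates
#'
#' @param model a [StructureModel].
#' @param chain,resno residue address.
#' @return numeric vector of chi angles (degrees), length given by the
#'   residue's chemistry.
#' @export
measureChiAngles <- function(model, chain, resno) {
  a <- atoms(model)
  idx <- .residueAtoms(a, chain, resno)
  if (!length(idx)) stop("no such residue", call. = FALSE)
  res3 <- a$resname[idx[1L]]
  defs <- .CHI_DEFS[[res3]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(d) {
    ps <- lapply(d, function(nm) {
      p <- .getCoord(a, idx, nm)
      if (is.null(p)) stop(sprintf("atom %s missing from %s %d", nm, res3,
                                   resno), call. = FALSE)
      p
    })
    .dihedral(ps[[1L]], ps[[2L]], ps[[3L]], ps[[4L]])
  }, numeric(1))
}

#' Replace a residue's side chain
#'
#' Removes the old side-chain atoms and rebuilds the new residue's side
#' chain from ideal internal geometry and the supplied chi angles,
#' anchored at the N-CA-CB frame. Backbone atom coordinates are untouched.
#'
#' @param model a [StructureModel].
#' @param chain,resno residue address.
#' @param newAA target residue (one- or three-letter code).
#' @param chis numeric chi angles (degrees); length must match the target
#'   residue's chemistry. Ignored for Gly/Ala... (zero-chi residues).
#' @return the mutated [StructureModel].
#' @export
placeSidechain <- function(model, chain, resno, newAA, chis = numeric(0)) {
  a <- atoms(model)
  idx <- .residueAtoms(a, chain, resno)
  if (!length(idx))
    stop(sprintf("no residue %d in chain %s", resno, chain), call. = FALSE)
  res3 <- if (nchar(newAA) == 1L) unname(.AA3_FROM_1[toupper(newAA)])
          else toupper(newAA)
  if (is.na(res3) || !res3 %in% .AA3)
    stop(sprintf("unknown amino acid '%s'", newAA), call. = FALSE)
  N <- .getCoord(a, idx, "N"); CA <- .getCoord(a, idx, "CA")
  C <- .getCoord(a, idx, "C")
  for (nm in c("N", "CA", "C"))
    if (is.null(.getCoord(a, idx, nm)))
      stop(sprintf("backbone atom %s missing from %s %d", nm, chain, resno),
           call. = FALSE)
  sc <- .buildSidechain(res3, N, CA, C, chis)
  keep_bb <- idx[a$name[idx] %in% .PROTEIN_BACKBONE]
  drop <- setdiff(idx, keep_bb)
  a$resname[keep_bb] <- res3
  if (length(drop)) a <- a[-drop, , drop = FALSE]
  if (length(sc)) {
    xyz <- do.call(rbind, sc)
    add <- .makeAtomsDF(names(sc), rep(res3, length(sc)),
                        rep(chain, length(sc)), rep(resno, length(sc)), xyz)
    a <- rbind(a, add)
  }
  ## stable order: by chain, residue, backbone-first
  a <- a[order(a$chain, a$resno,
               match(a$name, c(.PROTEIN_BACKBONE, .DNA_ATOM_ORDER),
                     nomatch = 99L)), , drop = FALSE]
  a$serial <- seq_len(nrow(a))
  rownames(a) <- NULL
  new("StructureModel", atoms = a)
}

#' Count steric clashes of one residue's side chain
#'
#' Heavy-atom pairs between the residue's side-chain atoms and all atoms of
#' other residues closer than `clashRadius`.
#'
#' @param model a [StructureModel].
#' @param chain,resno residue address.
#' @param clashRadius Angstrom (default 2.5).
#' @return integer clash count.
#' @export
countClashes <- function(model, chain, resno, clashRadius = 2.5) {
  a <- atoms(model)
  idx <- .residueAtoms(a, chain, resno)
  sc <- idx[!a$name[idx] %in% .PROTEIN_BACKBONE & a$element[idx] != "H"]
  others <- setdiff(which(a$element != "H"), idx)
  if (!length(sc) || !length(others)) return(0L)
  P <- as.matrix(a[sc, c("x", "y", "z")])
  Q <- as.matrix(a[others, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
        outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * P %*% t(Q)
  sum(d2 < clashRadius^2)
}

#' Choose the least-clashing rotamer for a mutation
#'
#' Places every library rotamer of the target residue at the site and
#' counts heavy-atom clashes against the rest of the structure; returns the
#' rotamer minimizing the clash count, ties broken by higher library
#' frequency, then by library order. Equivalent to an exhaustive scan.
#'
#' @param model a [StructureModel].
#' @param chain,resno site address.
#' @param newAA target residue (one- or three-letter).
#' @param library rotamer data.frame (see [defaultRotamerLibrary]).
#' @param clashRadius heavy-atom clash cutoff, Angstrom.
#' @return list with `chis`, `frequency`, `index` (row in the residue's
#'   library subset), `clashes` and `model` (the mutated structure).
#' @export
chooseRotamer <- function(model, chain, resno, newAA,
                          library = defaultRotamerLibrary(),
                          clashRadius = 2.5) {
  res3 <- if (nchar(newAA) == 1L) unname(.AA3_FROM_1[toupper(newAA)])
          else toupper(newAA)
  rows <- which(library$resname == res3)
  if (!length(rows))
    stop(sprintf("rotamer library has no entry for %s", res3), call. = FALSE)
  best <- NULL
  for (k in seq_along(rows)) {
    chis <- .rotamerChis(library[rows[k], , drop = FALSE])
    cand <- placeSidechain(model, chain, resno, res3, chis)
    cl <- countClashes(cand, chain, resno, clashRadius)
    fr <- library$frequency[rows[k]]
    if (is.null(best) || cl < best$clashes ||
        (cl == best$clashes && fr > best$frequency)) {
      best <- list(chis = chis, frequency = fr, index = k, clashes = cl,
                   model = cand)
    }
  }
  best
}

#' Thread a recognition helix onto a template complex
#'
#' Applies the helix's mutations site by site in 5'->3' finger order, each
#' with clash-minimizing rotamer selection. Sites whose template residue
#' already matches the helix are left untouched, so applying the template's
#' own helix is the identity.
#'
#' @param model template [StructureModel].
#' @param helix a [RecognitionHelix].
#' @param positionMap position map (see [defaultPositionMap]).
#' @param library rotamer library.
#' @param positions helix positions mutated (default -1, +3, +6).
#' @param clashRadius clash cutoff, Angstrom.
#' @return a [MutationResult].
#' @export
applyHelix <- function(model, helix, positionMap,
                       library = defaultRotamerLibrary(),
                       positions = c(-1L, 3L, 6L), clashRadius = 2.5) {
  muts <- helixToMutationSet(helix, model, positionMap, positions)
  sites <- list()
  cur <- model
  if (nrow(muts)) {
    muts <- muts[order(muts$resno), , drop = FALSE]
    for (i in seq_len(nrow(muts))) {
      ch <- chooseRotamer(cur, muts$chain[i], muts$resno[i], muts$to[i],
                          library, clashRadius)
      cur <- ch$model
      sites[[i]] <- data.frame(
        chain = muts$chain[i], resno = muts$resno[i],
        position = muts$position[i], from = muts$from[i], to = muts$to[i],
        rotamer = ch$index, clashes = ch$clashes, stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chain = character(), resno = integer(), position = integer(),
               from = character(), to = character(), rotamer = integer(),
               clashes = integer(), stringsAsFactors = FALSE)
  new("MutationResult", model = cur, sites = sites)
}

## ---- peptide backbone builder --------------------------------------------

#' Build an idealized alpha-helical peptide
#'
#' Constructs backbone atoms (N, CA, C, O) residue by residue at ideal
#' alpha-helix dihedrals (phi -57, psi -47, omega 180) and then adds side
#' chains with the highest-frequency library rotamer. Used to assemble
#' synthetic recognition-helix chains for template complexes and fixtures.
#'
#' @param sequence one-letter amino-acid string.
#' @param chain chain id (default `"P"`).
#' @param startResno first residue number.
#' @param library rotamer library for side-chain placement; `NULL` for a
#'   backbone-only (poly-Gly-like) chain that still carries the requested
#'   residue names.
#' @param phi,psi backbone dihedrals, degrees.
#' @return a [StructureModel].
#' @export
buildPeptide <- function(sequence, chain = "P", startResno = 1L,
                         library = defaultRotamerLibrary(),
                         phi = -57, psi = -47) {
  res1 <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(res1 %in% .AA1)) stop("unknown amino acid in sequence", call. = FALSE)
  res3 <- .AA3_FROM_1[res1]
  n <- length(res3)
  Ns <- CAs <- Cs <- Os <- vector("list", n)
  Ns[[1L]] <- c(0, 0, 0); CAs[[1L]] <- c(1.46, 0, 0)
  Cs[[1L]] <- .placeAtom(c(0, 1, 0), Ns[[1L]], CAs[[1L]], 1.52, 111.2, 122)
  for (i in seq_len(n)) {
    if (i > 1L) {
      Ns[[i]] <- .placeAtom(Ns[[i - 1L]], CAs[[i - 1L]], Cs[[i - 1L]],
                            1.33, 116.2, psi)
      CAs[[i]] <- .placeAtom(CAs[[i - 1L]], Cs[[i - 1L]], Ns[[i]],
                             1.46, 121.7, 180)
      Cs[[i]] <- .placeAtom(Cs[[i - 1L]], Ns[[i]], CAs[[i]],
                            1.52, 111.2, phi)
    }
    Os[[i]] <- .placeAtom(Ns[[i]], CAs[[i]], Cs[[i]], 1.23, 120.8, psi + 180)
  }
  nm <- rep(c("N", "CA", "C", "O"), n)
  rn <- rep(res3, each = 4L)
  no <- rep(startResno + seq_len(n) - 1L, each = 4L)
  xyz <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(Ns[[i]], CAs[[i]], Cs[[i]], Os[[i]])))
  m <- new("StructureModel",
           atoms = .makeAtomsDF(nm, rn, rep(chain, length(nm)), no, xyz))
  if (!is.null(library)) {
    for (i in seq_len(n)) {
      if (.N_CHI[[res3[i]]] == 0L && res3[i] != "ALA") next
      rows <- which(library$resname == res3[i])
      if (!length(rows)) next
      top <- rows[which.max(library$frequency[rows])]
      chis <- .rotamerChis(library[top, , drop = FALSE])
      m <- placeSidechain(m, chain, startResno + i - 1L, res3[i], chis)
    }
  }
  m
}
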