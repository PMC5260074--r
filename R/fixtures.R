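#' @include dna_model.R mutator.R ihbe_scorer.R
NULL

## Synthetic protein-DNA fixtures with hydrogen bonds planted at exact
## (distance, angle, class) geometry, so the scorer's output is known in
## closed form. Fixtures use real residue and atom names (Lys NZ, Arg NH1,
## guanine O6, ...) so the chemistry table is exercised, not bypassed.

## Atom identities used to realize each planted-bond class. Rotationally
## free donors realize theta = 0 exactly by convention; the Arg
## guanidinium NH1 (sp2, fixed hydrogens) realizes a controlled nonzero
## theta. O-O bonds only have rotatable donors (hydroxyls), so nonzero
## theta cannot be planted for that class.
.PLANT_SPECS <- list(
  "N-N" = list(rot = list(res = "LYS", atom = "NZ"),
               sp2 = list(res = "ARG", atom = "NH1"),
               acc = list(res = "DG", atom = "N7")),
  "N-O" = list(rot = list(res = "LYS", atom = "NZ"),
               sp2 = list(res = "ARG", atom = "NH1"),
               acc = list(res = "DG", atom = "O6")),
  "O-O" = list(rot = list(res = "SER", atom = "OG"),
               sp2 = NULL,
               acc = list(res = "DG", atom = "O6")))

## Atom catalogue for random decoy structures: (resname, atom) pairs over
## elements C/N/O covering donors, acceptors, sp2 donors without placed
## context (theta falls back to 0) and carbons.
.RANDOM_CATALOG <- list(
  protein = list(c("ALA", "CB"), c("LYS", "NZ"), c("ASP", "OD1"),
                 c("SER", "OG"), c("GLN", "OE1"), c("ASN", "ND2"),
                 c("ARG", "NH1"), c("GLY", "CA"), c("THR", "OG1")),
  dna = list(c("DG", "O6"), c("DG", "N7"), c("DG", "N1"), c("DT", "O2"),
             c("DT", "O4"), c("DA", "N6"), c("DA", "N3"), c("DC", "N3"),
             c("DC", "O2"), c("DT", "C7")))

.fixtureAtom <- function(name, resname, chain, resno, p) {
  list(name = name, resname = resname, chain = chain, resno = resno,
       x = p[1L], y = p[2L], z = p[3L])
}

.atomsFromList <- function(lst) {
  nm <- vapply(lst, `[[`, character(1), "name")
  rn <- vapply(lst, `[[`, character(1), "resname")
  ch <- vapply(lst, `[[`, character(1), "chain")
  no <- vapply(lst, `[[`, numeric(1), "resno")
  xyz <- cbind(vapply(lst, `[[`, numeric(1), "x"),
               vapply(lst, `[[`, numeric(1), "y"),
               vapply(lst, `[[`, numeric(1), "z"))
  .makeAtomsDF(nm, rn, ch, no, xyz)
}

#' Build a synthetic interface with planted hydrogen bonds
#'
#' Constructs a minimal protein/DNA complex in which each requested bond's
#' donor-acceptor geometry matches the given (class, d, theta) exactly, so
#' the total interfacial energy is known in closed form. Decoy atoms that
#' must never score (carbon pairs, pairs beyond the cutoff,
#' non-donor/acceptor pairs) can be added; planted sites are spaced so
#' that no unintended pair falls inside the screening cutoff.
#'
#' @param bonds data.frame with columns `class` (`"N-N"`, `"N-O"`,
#'   `"O-O"`), `d` (Angstrom) and `theta` (degrees; must be 0 for `O-O`,
#'   at most 60 otherwise), optional `finger` (1-3, default 1).
#' @param decoys number of decoy sites (cycled over the three decoy
#'   kinds).
#' @param params an [HBondParams] (supplies the closed-form energies and
#'   the cutoff used to place far decoys).
#' @return list with `model` (a [StructureModel]), `expected` (analytic
#'   total energy, kcal/mol) and `bonds` (the input annotated with
#'   per-bond expected energies).
#' @examples
#' fx <- makeFixture(data.frame(class = c("N-N", "N-O"), d = c(3.2, 3.0),
#'                              theta = 0))
#' fx$expected  # -4.8
#' @export
makeFixture <- function(bonds, decoys = 0L, params = hbondParams()) {
  stopifnot(is.data.frame(bonds),
            all(c("class", "d", "theta") %in% names(bonds)))
  if (!"finger" %in% names(bonds)) bonds$finger <- rep(1L, nrow(bonds))
  if (any(!bonds$class %in% names(.PLANT_SPECS)))
    stop("unknown bond class", call. = FALSE)
  if (any(bonds$d < 1.5))
    stop("unrealizable geometry: donor-acceptor distance below 1.5 A",
         call. = FALSE)
  if (any(bonds$theta < 0 | bonds$theta > 180))
    stop("theta must lie in [0, 180] degrees", call. = FALSE)
  at <- list()
  energies <- numeric(nrow(bonds))
  spacing <- 4 * params@cutoff
  for (k in seq_len(nrow(bonds))) {
    cls <- bonds$class[k]; d <- bonds$d[k]; th <- bonds$theta[k]
    spec <- .PLANT_SPECS[[cls]]
    o <- c(0, 0, spacing * (k - 1L))
    if (th == 0 && !is.null(spec$rot)) {
      ## rotatable donor: H points at the acceptor by convention
      at[[length(at) + 1L]] <- .fixtureAtom(spec$rot$atom, spec$rot$res,
                                            "P", k, o)
      at[[length(at) + 1L]] <- .fixtureAtom(spec$acc$atom, spec$acc$res,
                                            "D", k, o + c(d, 0, 0))
    } else {
      if (is.null(spec$sp2))
        stop(sprintf(
          "unrealizable geometry: class %s has only rotatable donors (theta must be 0)",
          cls), call. = FALSE)
      if (th > 60)
        stop("unrealizable geometry: planted theta above 60 degrees",
             call. = FALSE)
      ## Arg guanidinium: NH1 at the origin, CZ along -x, NE completing the
      ## sp2 plane; idealized H directions then sit at +-60 deg in the
      ## xy-plane and the acceptor at (60 - theta) deg realizes theta.
      D <- o
      CZ <- o + c(-1.33, 0, 0)
      NE <- CZ + 1.33 * c(cos(120 * .DEG), sin(120 * .DEG), 0)
      ang <- (60 - th) * .DEG
      A <- o + d * c(cos(ang), sin(ang), 0)
      if (.vnorm(NE - A) <= params@cutoff)
        stop("unrealizable geometry: planted acceptor clashes with donor context",
             call. = FALSE)
      at[[length(at) + 1L]] <- .fixtureAtom("NH1", "ARG", "P", k, D)
      at[[length(at) + 1L]] <- .fixtureAtom("CZ", "ARG", "P", k, CZ)
      at[[length(at) + 1L]] <- .fixtureAtom("NE", "ARG", "P", k, NE)
      at[[length(at) + 1L]] <- .fixtureAtom(spec$acc$atom, spec$acc$res,
                                            "D", k, A)
    }
    energies[k] <- hbondEnergy(d, th, cls, params)
  }
  nb <- nrow(bonds)
  for (j in seq_len(decoys)) {
    o <- c(0, 0, spacing * (nb + j - 1L))
    resno <- nb + j
    kind <- (j - 1L) %% 3L
    if (kind == 0L) {
      ## carbon pair inside the cutoff: ignored by the carbon rule
      at[[length(at) + 1L]] <- .fixtureAtom("CB", "ALA", "P", resno, o)
      at[[length(at) + 1L]] <- .fixtureAtom("O2", "DT", "D", resno,
                                            o + c(2.9, 0, 0))
    } else if (kind == 1L) {
      ## donor/acceptor pair just beyond the cutoff: never screened
      at[[length(at) + 1L]] <- .fixtureAtom("NZ", "LYS", "P", resno, o)
      at[[length(at) + 1L]] <- .fixtureAtom("O6", "DG", "D", resno,
                                            o + c(params@cutoff + 0.5, 0, 0))
    } else {
      ## donor-donor pair: no acceptor, rejected at role resolution
      at[[length(at) + 1L]] <- .fixtureAtom("NZ", "LYS", "P", resno, o)
      at[[length(at) + 1L]] <- .fixtureAtom("N2", "DG", "D", resno,
                                            o + c(2.9, 0, 0))
    }
  }
  model <- new("StructureModel", atoms = .atomsFromList(at))
  list(model = model, expected = sum(energies),
       bonds = cbind(bonds, expected_energy = energies))
}

#' Random atom cloud for oracle-equivalence testing
#'
#' Seeded random structure: atoms drawn from a catalogue of real
#' (residue, atom) identities over elements C/N/O, half on a protein
#' chain and half on a DNA chain, placed uniformly in a box sized so that
#' many pairs straddle the screening cutoff. Used to compare the pipeline
#' scorer against an independent exhaustive oracle.
#'
#' @param nAtoms total atom count (>= 2).
#' @param seed integer seed (reproducible).
#' @param boxSize box edge, Angstrom (default scales with `nAtoms`).
#' @return a [StructureModel].
#' @export
randomFixture <- function(nAtoms, seed, boxSize = NULL) {
  stopifnot(nAtoms >= 2L)
  set.seed(seed)
  if (is.null(boxSize)) boxSize <- max(7, round(nAtoms^(1 / 3) * 3.2, 1))
  np <- ceiling(nAtoms / 2); nd <- nAtoms - np
  at <- list()
  placed <- matrix(numeric(0), ncol = 3L)
  ## rejection-sample positions so no two atoms overlap (>= 1.5 A apart)
  draw <- function() {
    for (try in 1:200) {
      p <- runif(3L, 0, boxSize)
      if (!nrow(placed) ||
          min(sqrt(rowSums(sweep(placed, 2L, p)^2))) >= 1.5) {
        placed <<- rbind(placed, p)
        return(p)
      }
    }
    stop("box too crowded to place atoms 1.5 A apart", call. = FALSE)
  }
  for (i in seq_len(np)) {
    id <- .RANDOM_CATALOG$protein[[sample.int(length(.RANDOM_CATALOG$protein), 1L)]]
    at[[length(at) + 1L]] <- .fixtureAtom(id[2L], id[1L], "P", i, draw())
  }
  for (i in seq_len(nd)) {
    id <- .RANDOM_CATALOG$dna[[sample.int(length(.RANDOM_CATALOG$dna), 1L)]]
    at[[length(at) + 1L]] <- .fixtureAtom(id[2L], id[1L], "D", i, draw())
  }
  new("StructureModel", atoms = .atomsFromList(at))
}

#' Synthetic three-finger template complex
#'
#' Assembles a stand-in for a zinc-finger/DNA template: an idealized
#' B-DNA duplex of the target sequence plus three 7-residue alpha-helical
#' peptides (positions -1..+6), each placed with its side chains facing
#' one 3-bp sub-site from the major-groove side. The complex is synthetic
#' - a geometric scaffold for threading and scoring, not a crystallographic
#' model - but carries real residue chemistry throughout.
#'
#' @param target a 9-nt (modular layout) or 27-nt (synergistic)
#'   [DnaTarget] or plain sequence string.
#' @param helices character vector of three 7-letter helix codes placed at
#'   fingers 1-3 (default the classic Zif-268 helices).
#' @param approachDistance distance from each sub-site's base-edge
#'   centroid to the helix CA centroid, Angstrom.
#' @param library rotamer library used to build template side chains.
#' @return list with `model`, `positionMap` (protein chain `"P"`, helix
#'   starts 19/47/75), `dnaChain` (`"A"`) and `windows` (per-finger
#'   primary-strand residue numbers of the sub-sites).
#' @export
syntheticTemplateComplex <- function(target,
                                     helices = c("RSDELTR", "RSDHLTT",
                                                 "RSDERKR"),
                                     approachDistance = 6.5,
                                     library = defaultRotamerLibrary()) {
  seqstr <- if (is(target, "DnaTarget")) targetSequence(target) else
    .checkDnaString(target)
  n <- nchar(seqstr)
  if (!n %in% c(9L, 27L))
    stop("template target must be 9 or 27 nt", call. = FALSE)
  offset <- if (n == 9L) 0L else 9L   # synergistic: sub-sites after flank
  dna <- buildBDNA(seqstr)
  a <- atoms(dna)
  positionMap <- list(chain = "P", helix_start = c(19L, 47L, 75L))
  windows <- lapply(1:3, function(f) offset + (3L * f - 2L):(3L * f))
  prot <- list()
  for (f in 1:3) {
    w <- windows[[f]]
    edge <- a[a$chain == "A" & a$resno %in% w & !a$backbone, , drop = FALSE]
    cen <- colMeans(edge[, c("x", "y", "z")])
    axis_pt <- c(0, 0, cen[3L])
    out <- .unitv(c(cen[1L], cen[2L], 0))
    pep <- buildPeptide(helices[f], chain = positionMap$chain,
                        startResno = positionMap$helix_start[f] - 1L,
                        library = library)
    pa <- atoms(pep)
    ca <- as.matrix(pa[pa$name == "CA", c("x", "y", "z")])
    pcen <- colMeans(ca)
    ## helix principal axis -> DNA axis (z); then CB side toward the DNA
    ax <- .unitv(ca[nrow(ca), ] - ca[1L, ])
    v <- .vcross(ax, c(0, 0, 1))
    R1 <- if (.vnorm(v) < 1e-8) diag(3) else
      .rotationMatrix(v, .vecAngle(ax, c(0, 0, 1)))
    pep <- transformModel(pep, R1, -as.vector(R1 %*% pcen))
    pa <- atoms(pep)
    cb <- pa[pa$name == "CB", , drop = FALSE]
    if (nrow(cb)) {
      mean_cb <- colMeans(as.matrix(cb[, c("x", "y", "z")]))
      ca2 <- colMeans(as.matrix(pa[pa$name == "CA", c("x", "y", "z")]))
      side <- (mean_cb - ca2); side[3L] <- 0
      if (.vnorm(side) > 1e-8) {
        want <- -out
        ang <- atan2(.vcross(.unitv(side), want)[3L],
                     sum(.unitv(side) * want)) / .DEG
        R2 <- .rotationMatrix(c(0, 0, 1), ang)
        pep <- transformModel(pep, R2)
      }
    }
    ## helix CA centroid lands approachDistance outside the sub-site edge
    pep <- transformModel(pep, diag(3), cen + approachDistance * out)
    prot[[f]] <- atoms(pep)
  }
  pall <- do.call(rbind, prot)
  all_atoms <- rbind(a, pall)
  all_atoms$serial <- seq_len(nrow(all_atoms))
  rownames(all_atoms) <- NULL
  model <- new("StructureModel", atoms = all_atoms)
  ## relax template side chains against the assembled complex
  if (!is.null(library)) {
    pres <- unique(all_atoms[all_atoms$kind == "protein", c("chain", "resno",
                                                            "resname")])
    for (i in seq_len(nrow(pres))) {
      if (.N_CHI[[pres$resname[i]]] == 0L) next
      model <- chooseRotamer(model, pres$chain[i], pres$resno[i],
                             pres$resname[i], library)$model
    }
  }
  list(model = model,
       positionMap = positionMap, dnaChain = "A", windows = windows)
}
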