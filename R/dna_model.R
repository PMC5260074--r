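#' @include geometry.R chemistry.R AllClasses.R
NULL

## Idealized B-form duplex builder. Base heavy-atom templates are computed
## from planar ring geometry (regular 6- and fused 5-rings, standard bond
## lengths for exocyclic substituents); Watson-Crick partners are placed
## with the purine N1 / pyrimidine N3 central hydrogen bond at 2.9 A, and
## successive base pairs are related by a twist about and rise along the
## helix axis. A fixed idealized sugar-phosphate template hangs off each
## glycosidic frame. Only the base-edge geometry matters for interface
## scoring; the backbone is carried for completeness and excluded from
## scoring by default.

.WC_N1N3 <- 2.9      # purine N1 to pyrimidine N3, Angstrom
.RING_SIDE <- 1.39   # aromatic ring edge, Angstrom

## Local backbone offsets (Angstrom) in the per-nucleotide glycosidic frame
## (origin C1', x toward C1' from the glycosidic N, z off the base plane).
.SUGAR_OFFSETS <- rbind(
  "C1'" = c(0.00, 0.00, 0.00),
  "O4'" = c(0.55, 1.25, 0.35),
  "C2'" = c(0.88, -1.05, 0.62),
  "C3'" = c(2.10, -0.62, 1.05),
  "C4'" = c(1.95, 0.92, 1.15),
  "C5'" = c(2.95, 1.35, 2.05),
  "O3'" = c(2.85, -1.48, 1.62),
  "O5'" = c(3.05, 0.95, 3.35),
  "P"   = c(4.30, 1.50, 4.05),
  "OP1" = c(5.50, 0.90, 3.65),
  "OP2" = c(4.20, 3.00, 3.95))

## Heavy-atom template of one base in its own plane (z = 0), as a named
## list of 3-vectors. Includes the glycosidic nitrogen ring and exocyclic
## atoms; C1' and the sugar template are attached afterwards.
.baseTemplate <- function(base) {
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  hex <- lapply(0:5, function(i) {
    a <- (90 - 60 * i) * pi / 180
    c(.RING_SIDE * cos(a), .RING_SIDE * sin(a), 0)
  })
  names(hex) <- hex_names
  ctr <- c(0, 0, 0)
  radial <- function(p, bond) p + bond * .unitv(p - ctr)
  at <- hex
  if (base %in% c("C", "T")) {
    at[["O2"]] <- radial(hex[["C2"]], 1.23)
    if (base == "C") {
      at[["N4"]] <- radial(hex[["C4"]], 1.34)
    } else {
      at[["O4"]] <- radial(hex[["C4"]], 1.23)
      at[["C7"]] <- radial(hex[["C5"]], 1.50)
    }
  } else {
    pent <- .completeRegularRing(hex[["C4"]], hex[["C5"]], 5L, awayFrom = ctr)
    at[["N7"]] <- pent[[1L]]
    at[["C8"]] <- pent[[2L]]
    at[["N9"]] <- pent[[3L]]
    if (base == "A") {
      at[["N6"]] <- radial(hex[["C6"]], 1.34)
    } else {
      at[["O6"]] <- radial(hex[["C6"]], 1.23)
      at[["N2"]] <- radial(hex[["C2"]], 1.34)
    }
  }
  ## glycosidic C1' radially off the attachment nitrogen
  if (base %in% c("A", "G")) {
    pent_ctr <- Reduce(`+`, at[c("C4", "C5", "N7", "C8", "N9")]) / 5
    at[["C1'"]] <- at[["N9"]] + 1.47 * .unitv(at[["N9"]] - pent_ctr)
  } else {
    at[["C1'"]] <- at[["N1"]] + 1.47 * .unitv(at[["N1"]] - ctr)
  }
  at
}

.BASE_TEMPLATES <- lapply(setNames(nm = c("A", "C", "G", "T")), .baseTemplate)

## 2-D (in-plane) rotation of a template's coordinates.
.rotTemplate <- function(at, ang) {
  R <- .rotationMatrix(c(0, 0, 1), ang)
  lapply(at, function(p) as.vector(R %*% p))
}

.shiftTemplate <- function(at, t) lapply(at, function(p) p + t)

## One Watson-Crick pair in the pair frame: midpoint of the central N1-N3
## hydrogen bond at the origin, bond axis along x, strand-A base on -x.
## Returns list(A = template, B = template) of atom coordinate lists.
.basePairTemplate <- function(baseA) {
  baseB <- .BASE_COMPLEMENT[[baseA]]
  pur <- if (baseA %in% c("A", "G")) baseA else baseB
  pyr <- if (baseA %in% c("C", "T")) baseA else baseB
  P <- .BASE_TEMPLATES[[pur]]
  Q <- .BASE_TEMPLATES[[pyr]]
  ## purine: N1 to origin, WC-edge outward direction to +x
  outP <- .unitv(P[["N1"]])       # hexagon centered at origin in template
  angP <- -atan2(outP[2L], outP[1L]) / .DEG
  P <- .shiftTemplate(.rotTemplate(P, angP), -as.vector(
    .rotationMatrix(c(0, 0, 1), angP) %*% P[["N1"]]))
  ## pyrimidine: edge outward to -x, N3 placed across the central bond;
  ## this orientation brings the flanking donors/acceptors (O6/N4, N2/O2,
  ## O4/N6) face to face and puts both glycosidic bonds on the same side
  outQ <- .unitv(Q[["N3"]])
  angQ <- 180 - atan2(outQ[2L], outQ[1L]) / .DEG
  Q <- .rotTemplate(Q, angQ)
  Q <- .shiftTemplate(Q, c(.WC_N1N3, 0, 0) - Q[["N3"]])
  ## center the pair on the helix axis
  mid <- c(.WC_N1N3 / 2, 0, 0)
  P <- .shiftTemplate(P, -mid)
  Q <- .shiftTemplate(Q, -mid)
  pair <- if (baseA %in% c("A", "G")) list(A = P, B = Q) else list(A = Q, B = P)
  if (baseA %in% c("C", "T")) {
    ## pseudo-dyad flip: strand A keeps the -x side
    flip <- function(at) lapply(at, function(p) c(-p[1L], p[2L], -p[3L]))
    pair <- list(A = flip(pair$A), B = flip(pair$B))
  }
  pair
}

## Attach the idealized sugar-phosphate template to a placed base. zdir
## selects which side of the base plane the sugar extends to, so that the
## two strands' backbones run antiparallel along the helix axis.
.attachSugar <- function(at, base, zdir = 1) {
  ngly <- if (base %in% c("A", "G")) "N9" else "N1"
  nbr <- if (base %in% c("A", "G")) "C4" else "C2"
  xhat <- .unitv(at[["C1'"]] - at[[ngly]])
  v <- at[[nbr]] - at[[ngly]]
  yhat <- .unitv(v - sum(v * xhat) * xhat)
  zhat <- .vcross(xhat, yhat)
  if (zhat[3L] * zdir < 0) zhat <- -zhat
  for (nm in rownames(.SUGAR_OFFSETS)) {
    if (nm == "C1'") next
    o <- .SUGAR_OFFSETS[nm, ]
    at[[nm]] <- at[["C1'"]] + o[1L] * xhat + o[2L] * yhat + o[3L] * zhat
  }
  at
}

.DNA_ATOM_ORDER <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                     "O3'", "C2'", "C1'")

## Assemble an atom data.frame from a list of records
## (name, resname, chain, resno, x, y, z).
.makeAtomsDF <- function(name, resname, chain, resno, xyz) {
  resname <- .canonResname(resname)
  el <- .elementFromName(name)
  kind <- .kindFromResname(resname)
  bb <- (kind == "protein" & name %in% .PROTEIN_BACKBONE) |
        (kind == "nucleotide" & name %in% .DNA_BACKBONE)
  data.frame(serial = seq_along(name), name = name, resname = resname,
             chain = chain, resno = as.integer(resno),
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             element = el, kind = kind, backbone = bb,
             stringsAsFactors = FALSE)
}

#' Build an idealized B-form DNA duplex from sequence
#'
#' Generates a straight two-chain B-DNA model: one base pair per input
#' base, successive pairs related by a fixed helical twist and rise, chain
#' A carrying the input sequence 5'->3' and chain B its reverse complement.
#' Heavy atoms only; polar hydrogens are placed implicitly by the scorer.
#'
#' @param sequence primary-strand ACGT string (5'->3').
#' @param twist helical twist per base-pair step, degrees (default 36).
#' @param rise helical rise per step, Angstrom (default 3.38).
#' @return a [StructureModel] with chains `A` and `B`.
#' @examples
#' m <- buildBDNA("GCGTGGGCG")
#' nAtoms(m)
#' @export
buildBDNA <- function(sequence, twist = 36, rise = 3.38) {
  sequence <- .checkDnaString(sequence)
  if (!nchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  stopifnot(is.finite(twist), is.finite(rise), rise > 0)
  bases <- strsplit(sequence, "")[[1L]]
  n <- length(bases)
  recA <- list(); recB <- list()
  for (i in seq_len(n)) {
    pair <- .basePairTemplate(bases[i])
    baseB <- .BASE_COMPLEMENT[[bases[i]]]
    atA <- .attachSugar(pair$A, bases[i], zdir = 1)
    atB <- .attachSugar(pair$B, baseB, zdir = -1)
    R <- .rotationMatrix(c(0, 0, 1), twist * (i - 1L))
    t <- c(0, 0, rise * (i - 1L))
    place <- function(at) lapply(at, function(p) as.vector(R %*% p) + t)
    atA <- place(atA); atB <- place(atB)
    ordA <- c(.DNA_ATOM_ORDER, setdiff(names(atA), .DNA_ATOM_ORDER))
    ordB <- c(.DNA_ATOM_ORDER, setdiff(names(atB), .DNA_ATOM_ORDER))
    recA[[i]] <- list(name = ordA, resname = paste0("D", bases[i]),
                      resno = i, xyz = do.call(rbind, atA[ordA]))
    recB[[i]] <- list(name = ordB, resname = paste0("D", baseB),
                      resno = n + 1L - i, xyz = do.call(rbind, atB[ordB]))
  }
  recB <- rev(recB)   # chain B written 5'->3' in its own numbering
  nm <- c(unlist(lapply(recA, `[[`, "name")),
          unlist(lapply(recB, `[[`, "name")))
  rn <- c(unlist(lapply(recA, function(r) rep(r$resname, length(r$name)))),
          unlist(lapply(recB, function(r) rep(r$resname, length(r$name)))))
  no <- c(unlist(lapply(recA, function(r) rep(r$resno, length(r$name)))),
          unlist(lapply(recB, function(r) rep(r$resno, length(r$name)))))
  ch <- rep(c("A", "B"), c(sum(lengths(lapply(recA, `[[`, "name"))),
                           sum(lengths(lapply(recB, `[[`, "name")))))
  xyz <- rbind(do.call(rbind, lapply(recA, `[[`, "xyz")),
               do.call(rbind, lapply(recB, `[[`, "xyz")))
  new("StructureModel", atoms = .makeAtomsDF(nm, rn, ch, no, xyz))
}

#' Sequence of a DNA chain in a model
#'
#' Reads residue names of the requested chain in residue-number order and
#' returns the one-letter base string (5'->3').
#'
#' @param model a [StructureModel].
#' @param chain chain id (default `"A"`).
#' @return ACGT string.
#' @export
dnaSequence <- function(model, chain = "A") {
  a <- atoms(model)
  a <- a[a$chain == chain & a$kind == "nucleotide", ]
  if (!nrow(a)) stop(sprintf("chain %s has no nucleotides", chain), call. = FALSE)
  res <- unique(a[order(a$resno), c("resno", "resname")])
  paste(sub("^D", "", res$resname), collapse = "")
}

#' Recompute helical parameters from a duplex model
#'
#' Estimates the per-step twist and rise of a built duplex from the central
#' Watson-Crick bond anchors (purine N1, pyrimidine N3) of successive base
#' pairs. The estimate is rigid-motion invariant and recovers the build
#' parameters exactly on an ideal model.
#'
#' @param model a two-chain duplex [StructureModel] from [buildBDNA].
#' @return list with `twist` and `rise` (means over steps) plus per-step
#'   vectors `twist_steps`, `rise_steps`.
#' @export
helicalParameters <- function(model) {
  a <- atoms(model)
  nuc <- a[a$kind == "nucleotide", ]
  if (!nrow(nuc)) stop("model has no nucleotides", call. = FALSE)
  n <- max(nuc$resno[nuc$chain == "A"])
  anchorA <- matrix(NA_real_, n, 3L); anchorB <- anchorA
  for (i in seq_len(n)) {
    ra <- nuc[nuc$chain == "A" & nuc$resno == i, ]
    rb <- nuc[nuc$chain == "B" & nuc$resno == n + 1L - i, ]
    pick <- function(r) {
      nm <- if (r$resname[1L] %in% c("DA", "DG")) "N1" else "N3"
      as.numeric(r[r$name == nm, c("x", "y", "z")])
    }
    anchorA[i, ] <- pick(ra); anchorB[i, ] <- pick(rb)
  }
  if (n < 2L) stop("need at least 2 base pairs to estimate step parameters",
                   call. = FALSE)
  mids <- (anchorA + anchorB) / 2
  vs <- anchorB - anchorA
  rise_steps <- numeric(n - 1L); twist_steps <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    u <- mids[i + 1L, ] - mids[i, ]
    rise_steps[i] <- .vnorm(u)
    u <- .unitv(u)
    proj <- function(v) v - sum(v * u) * u
    v1 <- proj(vs[i, ]); v2 <- proj(vs[i + 1L, ])
    ang <- atan2(sum(.vcross(v1, v2) * u), sum(v1 * v2)) / .DEG
    twist_steps[i] <- (ang + 360) %% 360
  }
  list(twist = mean(twist_steps), rise = mean(rise_steps),
       twist_steps = twist_steps, rise_steps = rise_steps)
}

#' Write a structure as a PDB file
#'
#' Standard ATOM records with unit occupancy and 1-based residue numbering,
#' written through bio3d. The file re-parses with [readPDB] to an
#' equivalent model (coordinates at PDB 3-decimal precision).
#'
#' @param model a non-empty [StructureModel].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(model, path) {
  stopifnot(is(model, "StructureModel"))
  a <- atoms(model)
  if (!nrow(a)) stop("refusing to write an empty model", call. = FALSE)
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Batch-build DNA target models
#'
#' Builds a B-DNA model for each target and writes one PDB per target into
#' `dir`, named `<mode>_<slot>_<triplet>.pdb`.
#'
#' @param targets list of [DnaTarget] objects (see [enumerateTargets]).
#' @param dir output directory, created if needed.
#' @param twist,rise helical parameters passed to [buildBDNA].
#' @return character vector of the files written.
#' @export
writeTargetModels <- function(targets, dir, twist = 36, rise = 3.38) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(targets, function(tg) {
    path <- file.path(dir, paste0(targetId(tg), ".pdb"))
    writePDB(buildBDNA(targetSequence(tg), twist, rise), path)
    path
  }, character(1))
}
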