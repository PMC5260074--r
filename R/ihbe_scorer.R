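#' @include AllClasses.R structure_io.R
NULL

## Interfacial hydrogen-bond detection and the 10-12 potential scorer.
## A bond requires one amino-acid atom and one nucleotide atom, both
## non-carbon N/O/S donors/acceptors, heavy-atom distance below the 3.5 A
## (350 pm) screening cutoff, and a donor-hydrogen geometry within 90
## degrees of linearity. Bond energies are summed per complex; the
## absolute value of the signed total is the ranking score.

#' Construct hydrogen-bond scoring parameters
#'
#' Defaults are the AMBER99-style optimum energies/lengths per element-pair
#' class and the 3.5 Angstrom heavy-atom screening cutoff.
#'
#' @param epsilon named numeric (kcal/mol) for classes `N-N`, `N-O`, `O-O`.
#' @param dOpt named numeric (Angstrom), same classes.
#' @param cutoff heavy-atom donor-acceptor screen, Angstrom.
#' @param thetaMax reject bonds whose deviation from linearity exceeds this
#'   (degrees); keeps anti-aligned geometries from scoring favorably.
#' @param sulfurAs element class sulfur maps to (`"O"` default).
#' @param includeBackbone score main-chain/sugar-phosphate polar atoms.
#' @param hMode `"idealized"` or `"strict"` hydrogen treatment.
#' @return an [HBondParams].
#' @examples
#' hbondParams()
#' @export
hbondParams <- function(epsilon = c("N-N" = 2.0, "N-O" = 2.8, "O-O" = 4.0),
                        dOpt = c("N-N" = 3.2, "N-O" = 3.0, "O-O" = 2.8),
                        cutoff = 3.5, thetaMax = 90, sulfurAs = "O",
                        includeBackbone = FALSE, hMode = "idealized") {
  new("HBondParams", epsilon = epsilon, dOpt = dOpt, cutoff = cutoff,
      thetaMax = thetaMax, sulfurAs = sulfurAs,
      includeBackbone = includeBackbone, hMode = hMode)
}

#' Hydrogen-bond energy of one donor-acceptor pair
#'
#' The 10-12-style potential
#' \deqn{\Delta G = \epsilon \left[3 (d'/d)^8 - 4 (d'/d)^6\right] \cos^4\theta}
#' where d is the donor-acceptor distance, d' the class optimum, epsilon
#' the class well depth and theta the deviation of donor-H...acceptor from
#' linearity. At d = d', theta = 0 the energy is exactly -epsilon.
#'
#' @param d donor-acceptor distance, Angstrom (> 0).
#' @param theta deviation from linearity, degrees.
#' @param pairClass `"N-N"`, `"N-O"` or `"O-O"`.
#' @param params an [HBondParams].
#' @return energy in kcal/mol (vectorized over `d`/`theta`).
#' @examples
#' hbondEnergy(2.8, 0, "O-O")   # -4.0
#' hbondEnergy(3.0, 90, "N-O")  # 0
#' @export
hbondEnergy <- function(d, theta, pairClass, params = hbondParams()) {
  if (!pairClass %in% names(params@epsilon))
    stop(sprintf("unknown hydrogen-bond class '%s'", pairClass), call. = FALSE)
  stopifnot(all(d > 0))
  eps <- params@epsilon[[pairClass]]
  dopt <- params@dOpt[[pairClass]]
  r <- dopt / d
  ## cospi gives an exact zero at theta = 90
  eps * (3 * r^8 - 4 * r^6) * cospi(theta / 180)^4
}

## Element-pair class from donor/acceptor elements, with sulfur mapped to
## its configured stand-in.
.pairClass <- function(el1, el2, params) {
  el1[el1 == "S"] <- params@sulfurAs
  el2[el2 == "S"] <- params@sulfurAs
  paste(pmin(el1, el2), pmax(el1, el2), sep = "-")
}

#' Interfacial atom pairs within the screening cutoff
#'
#' All (amino-acid atom, nucleotide atom) pairs closer than `cutoff`,
#' excluding every pair that contains a carbon (or hydrogen) atom, sorted
#' by distance. This is the raw geometric screen; donor/acceptor
#' resolution happens in [scoreComplex].
#'
#' @param protAtoms,dnaAtoms atom data.frames (rows of [atoms]) for the
#'   two sides of the interface.
#' @param cutoff Angstrom (default 3.5, i.e. 350 pm).
#' @return data.frame with the protein/DNA atom identifiers and `dist`.
#' @export
findInterfacePairs <- function(protAtoms, dnaAtoms, cutoff = 3.5) {
  p <- protAtoms[!protAtoms$element %in% c("C", "H"), , drop = FALSE]
  b <- dnaAtoms[!dnaAtoms$element %in% c("C", "H"), , drop = FALSE]
  empty <- data.frame(p_chain = character(), p_resno = integer(),
                      p_resname = character(), p_atom = character(),
                      d_chain = character(), d_resno = integer(),
                      d_resname = character(), d_atom = character(),
                      dist = numeric(), stringsAsFactors = FALSE)
  if (!nrow(p) || !nrow(b)) return(empty)
  P <- as.matrix(p[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(P^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(P)), rowSums(B^2)) - 2 * P %*% t(B)
  hit <- which(d2 < cutoff^2 + 1e-9, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  ## recompute hit distances directly (the outer-product form loses a few
  ## digits); then re-apply the cutoff exactly
  dist_exact <- sqrt(rowSums((P[hit[, 1L], , drop = FALSE] -
                              B[hit[, 2L], , drop = FALSE])^2))
  keep <- dist_exact < cutoff
  hit <- hit[keep, , drop = FALSE]
  dist_exact <- dist_exact[keep]
  if (!nrow(hit)) return(empty)
  out <- data.frame(
    p_chain = p$chain[hit[, 1L]], p_resno = p$resno[hit[, 1L]],
    p_resname = p$resname[hit[, 1L]], p_atom = p$name[hit[, 1L]],
    d_chain = b$chain[hit[, 2L]], d_resno = b$resno[hit[, 2L]],
    d_resname = b$resname[hit[, 2L]], d_atom = b$name[hit[, 2L]],
    dist = dist_exact, stringsAsFactors = FALSE)
  out[order(out$dist), , drop = FALSE]
}

## Idealized hydrogen directions (unit vectors) for a donor atom row of a
## classified atom table. NULL means a rotationally free donor (hydroxyl,
## thiol, ammonium) or missing geometric context: by convention its H
## points at the acceptor (theta = 0).
.donorHDirections <- function(classified, donorIdx) {
  row <- classified[donorIdx, ]
  if (isTRUE(row$rotatable)) return(NULL)
  if (is.na(row$ctx1) || row$nnbr < 1L) return(NULL)
  res <- classified[classified$chain == row$chain &
                    classified$resno == row$resno, , drop = FALSE]
  getp <- function(nm) {
    j <- which(res$name == nm)
    if (!length(j)) return(NULL)
    as.numeric(res[j[1L], c("x", "y", "z")])
  }
  D <- as.numeric(row[, c("x", "y", "z")])
  p1 <- getp(row$ctx1)
  if (is.null(p1)) return(NULL)
  if (row$nnbr >= 2L) {
    p2 <- getp(row$ctx2)
    if (is.null(p2)) return(NULL)
    ## two in-plane heavy neighbours: single H on the external bisector
    dir <- -( .unitv(p1 - D) + .unitv(p2 - D) )
    if (.vnorm(dir) < 1e-8) return(NULL)
    return(matrix(.unitv(dir), nrow = 1L))
  }
  ## one heavy neighbour (sp2 amine): two in-plane H at +-120 deg from it,
  ## plane defined by the neighbour's other substituent
  p2 <- if (!is.na(row$ctx2)) getp(row$ctx2) else NULL
  if (is.null(p2)) return(NULL)
  u1 <- .unitv(p1 - D)
  w <- (p2 - D) - sum((p2 - D) * u1) * u1
  if (.vnorm(w) < 1e-8) return(NULL)
  w <- .unitv(w)
  h1 <- cos(120 * .DEG) * u1 + sin(120 * .DEG) * w
  h2 <- cos(120 * .DEG) * u1 - sin(120 * .DEG) * w
  rbind(h1, h2)
}

## Explicit-H directions for strict mode: unit vectors to H atoms within
## 1.25 A of the donor in the same residue.
.explicitHDirections <- function(classified, donorIdx) {
  row <- classified[donorIdx, ]
  D <- as.numeric(row[, c("x", "y", "z")])
  hs <- classified[classified$chain == row$chain &
                   classified$resno == row$resno &
                   classified$element == "H", , drop = FALSE]
  if (!nrow(hs)) return(matrix(numeric(0), ncol = 3L))
  dirs <- list()
  for (j in seq_len(nrow(hs))) {
    v <- as.numeric(hs[j, c("x", "y", "z")]) - D
    if (.vnorm(v) <= 1.25) dirs[[length(dirs) + 1L]] <- .unitv(v)
  }
  if (!length(dirs)) return(matrix(numeric(0), ncol = 3L))
  do.call(rbind, dirs)
}

## Deviation-from-linearity angle for donor at index dIdx donating to
## acceptor position A. Returns NA when strict mode finds no hydrogen.
.donorTheta <- function(classified, dIdx, A, params) {
  D <- as.numeric(classified[dIdx, c("x", "y", "z")])
  if (params@hMode == "strict") {
    dirs <- .explicitHDirections(classified, dIdx)
    if (!nrow(dirs)) return(NA_real_)
  } else {
    dirs <- .donorHDirections(classified, dIdx)
    if (is.null(dirs)) return(0)
  }
  min(apply(dirs, 1L, function(h) .vecAngle(A - D, h)))
}

## Resolve one geometric pair into a hydrogen bond (1-row data.frame) or
## NULL. Tries both donation directions where roles permit and keeps the
## more favorable one.
.resolvePair <- function(pair, classified, params) {
  ckey <- paste(classified$chain, classified$resno, classified$name)
  pi <- match(paste(pair$p_chain, pair$p_resno, pair$p_atom), ckey)
  bi <- match(paste(pair$d_chain, pair$d_resno, pair$d_atom), ckey)
  if (is.na(pi) || is.na(bi)) return(NULL)
  prole <- classified$role[pi]; brole <- classified$role[bi]
  cand <- list()
  if (prole %in% c("donor", "both") && brole %in% c("acceptor", "both"))
    cand[[length(cand) + 1L]] <- list(d = pi, a = bi)
  if (brole %in% c("donor", "both") && prole %in% c("acceptor", "both"))
    cand[[length(cand) + 1L]] <- list(d = bi, a = pi)
  if (!length(cand)) return(NULL)
  best <- NULL
  for (cc in cand) {
    A <- as.numeric(classified[cc$a, c("x", "y", "z")])
    th <- .donorTheta(classified, cc$d, A, params)
    if (is.na(th) || th > params@thetaMax) next
    cls <- .pairClass(classified$element[cc$d], classified$element[cc$a],
                      params)
    if (!cls %in% names(params@epsilon)) next
    en <- hbondEnergy(pair$dist, th, cls, params)
    if (is.null(best) || en < best$energy)
      best <- list(d = cc$d, a = cc$a, theta = th, class = cls, energy = en)
  }
  if (is.null(best)) return(NULL)
  lab <- function(i) sprintf("%s:%s%d:%s", classified$chain[i],
                             classified$resname[i], classified$resno[i],
                             classified$name[i])
  data.frame(donor = lab(best$d), acceptor = lab(best$a),
             dist = pair$dist, theta = best$theta, class = best$class,
             energy = best$energy, stringsAsFactors = FALSE)
}

#' Resolve a geometric atom pair into a hydrogen bond
#'
#' Keeps the pair only if one atom can donate and the other accept under
#' the chemistry table; computes the deviation-from-linearity angle after
#' idealized polar-hydrogen placement (rotationally free donors point
#' their H at the acceptor, theta = 0) and rejects anti-aligned geometry
#' (theta beyond `thetaMax`).
#'
#' @param pair one row of [findInterfacePairs] output.
#' @param model the [StructureModel] the pair came from.
#' @param params an [HBondParams].
#' @return 1-row bond data.frame (donor, acceptor, dist, theta, class,
#'   energy) or `NULL` when rejected.
#' @export
resolveHBond <- function(pair, model, params = hbondParams()) {
  classified <- classifyDonorAcceptor(model, params@includeBackbone)
  .resolvePair(pair, classified, params)
}

#' Score a protein-DNA complex by interfacial hydrogen-bond energy
#'
#' Runs the full detection pipeline: geometric pair screen (cutoff,
#' carbon exclusion), donor/acceptor resolution, per-bond 10-12 energies,
#' signed sum and absolute-value score.
#'
#' @param model a protein-DNA complex [StructureModel].
#' @param params an [HBondParams].
#' @param helixAtoms,baseAtoms optional atom data.frames restricting the
#'   interface (e.g. from [selectInterfaceResidues]); default all
#'   protein atoms vs all nucleotide atoms.
#' @param helixId,triplet,finger annotations carried into the record.
#' @return a [ScoreRecord].
#' @examples
#' fx <- makeFixture(data.frame(class = "O-O", d = 2.8, theta = 0))
#' bondScore(scoreComplex(fx$model))  # 4.0
#' @export
scoreComplex <- function(model, params = hbondParams(),
                         helixAtoms = NULL, baseAtoms = NULL,
                         helixId = NA_character_, triplet = NA_character_,
                         finger = NA_integer_) {
  a <- atoms(model)
  if (is.null(helixAtoms)) helixAtoms <- a[a$kind == "protein", , drop = FALSE]
  if (is.null(baseAtoms)) baseAtoms <- a[a$kind == "nucleotide", , drop = FALSE]
  pairs <- findInterfacePairs(helixAtoms, baseAtoms, params@cutoff)
  classified <- classifyDonorAcceptor(model, params@includeBackbone)
  bonds <- list()
  for (i in seq_len(nrow(pairs))) {
    b <- .resolvePair(pairs[i, ], classified, params)
    if (!is.null(b)) bonds[[length(bonds) + 1L]] <- b
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(donor = character(), acceptor = character(),
               dist = numeric(), theta = numeric(), class = character(),
               energy = numeric(), stringsAsFactors = FALSE)
  tot <- if (nrow(bonds)) sum(bonds$energy) else 0
  new("ScoreRecord", helixId = as.character(helixId),
      triplet = as.character(triplet), finger = as.integer(finger),
      bonds = bonds, totalEnergy = tot, score = abs(tot))
}

#' Write a per-complex bond report as TSV
#'
#' @param record a [ScoreRecord].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBondReport <- function(record, path) {
  stopifnot(is(record, "ScoreRecord"))
  utils::write.table(hbonds(record), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
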