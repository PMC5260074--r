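## Internal 3-D geometry helpers. All angles in degrees at the interface;
## radians only inside function bodies.

.DEG <- pi / 180

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.vnorm <- function(v) sqrt(sum(v * v))

.unitv <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

## Angle ABC at vertex B, degrees.
.angle3 <- function(a, b, c) {
  u <- .unitv(a - b); v <- .unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) / .DEG
}

## Angle between two direction vectors, degrees.
.vecAngle <- function(u, v) {
  u <- .unitv(u); v <- .unitv(v)
  acos(max(-1, min(1, sum(u * v)))) / .DEG
}

## Signed dihedral p1-p2-p3-p4, degrees in (-180, 180].
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) / .DEG
}

## NeRF atom placement: returns point d with |d-c| = bond,
## angle(b,c,d) = ang and dihedral(a,b,c,d) = dih (degrees).
.placeAtom <- function(a, b, c, bond, ang, dih) {
  ang <- ang * .DEG; dih <- dih * .DEG
  bc <- .unitv(c - b)
  n <- .unitv(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), -bond * sin(ang) * sin(dih))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Rotation matrix about unit axis by angle degrees (Rodrigues).
.rotationMatrix <- function(axis, ang) {
  u <- .unitv(axis); t <- ang * .DEG
  ct <- cos(t); st <- sin(t)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux * ux * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy * uy * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz * uz * (1 - ct)),
    nrow = 3L, byrow = TRUE)
}

## Apply rotation R (3x3) then translation t to an n x 3 coordinate matrix.
.transformCoords <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2L, -t)
}

#' Apply a rigid transform to a structure
#'
#' Rotates all atom coordinates by `R` and then translates by `t`. Used by
#' the property tests asserting that interface scores are invariant under
#' global rigid motion.
#'
#' @param model a [StructureModel].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector (Angstrom).
#' @return the transformed [StructureModel].
#' @export
transformModel <- function(model, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (nrow(a)) {
    xyz <- .transformCoords(as.matrix(a[, c("x", "y", "z")]), R, t)
    a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  }
  new("StructureModel", atoms = a)
}

#' Random rotation matrix
#'
#' Uniform random 3-D rotation, for rigid-invariance property tests.
#'
#' @param seed optional integer seed.
#' @return 3x3 rotation matrix.
#' @export
randomRotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ## QR of a Gaussian matrix, sign-corrected to det +1
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

## Given two adjacent vertices p1, p2 of a regular k-gon (planar, z = 0) and
## a reference point that must lie on the OPPOSITE side of edge p1-p2 from
## the polygon body, return the remaining k-2 vertices in order p2 -> p1.
.completeRegularRing <- function(p1, p2, k, awayFrom) {
  s <- .vnorm(p2 - p1)
  apothem <- s / (2 * tan(pi / k))
  mid <- (p1 + p2) / 2
  nvec <- c(-(p2 - p1)[2L], (p2 - p1)[1L], 0)
  nvec <- .unitv(nvec)
  if (sum((awayFrom - mid) * nvec) > 0) nvec <- -nvec
  center <- mid + apothem * nvec
  r <- .vnorm(p1 - center)
  a1 <- atan2(p1[2L] - center[2L], p1[1L] - center[1L])
  a2 <- atan2(p2[2L] - center[2L], p2[1L] - center[1L])
  ## step direction from p2 onward, continuing around the ring away from p1
  d <- a2 - a1
  d <- atan2(sin(d), cos(d))
  out <- vector("list", k - 2L)
  for (i in seq_len(k - 2L)) {
    ai <- a2 + i * d
    out[[i]] <- c(center[1L] + r * cos(ai), center[2L] + r * sin(ai), 0)
  }
  out
}
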