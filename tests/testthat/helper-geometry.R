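# Independent torsion measurement for chi round-trip checks: computed from
# plane normals with the sign from a scalar triple product, separate from
# any package code.

refDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(1, max(-1, cosv))) * 180 / pi
  if (sum(n1 * b3) > 0) ang <- -ang
  ang
}

# Smallest absolute angular difference, degrees.
angDiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Coordinates of one named atom of a residue.
atomCoord <- function(model, chain, resno, name) {
  a <- atoms(model)
  r <- a[a$chain == chain & a$resno == resno & a$name == name, ]
  stopifnot(nrow(r) == 1)
  as.numeric(r[, c("x", "y", "z")])
}
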