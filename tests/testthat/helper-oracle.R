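# Independent exhaustive-pair oracle for the interfacial hydrogen-bond
# energy. Re-states every scoring rule from scratch (own role table, own
# vector algebra, plain loops over all atom pairs); shares no code with the
# package's detection pipeline.

.OR_ROLES <- list(
  "LYS NZ"  = list(role = "donor", el = "N", rot = TRUE),
  "SER OG"  = list(role = "both", el = "O", rot = TRUE),
  "THR OG1" = list(role = "both", el = "O", rot = TRUE),
  "ASP OD1" = list(role = "acceptor", el = "O"),
  "GLN OE1" = list(role = "acceptor", el = "O"),
  "ASN ND2" = list(role = "donor", el = "N", ctx = c("CG", "OD1"), nn = 1),
  "ARG NH1" = list(role = "donor", el = "N", ctx = c("CZ", "NE"), nn = 1),
  "ARG NE"  = list(role = "donor", el = "N", ctx = c("CD", "CZ"), nn = 2),
  "DG O6"   = list(role = "acceptor", el = "O"),
  "DG N7"   = list(role = "acceptor", el = "N"),
  "DG N1"   = list(role = "donor", el = "N", ctx = c("C2", "C6"), nn = 2),
  "DG N2"   = list(role = "donor", el = "N", ctx = c("C2", "N1"), nn = 1),
  "DT O2"   = list(role = "acceptor", el = "O"),
  "DT O4"   = list(role = "acceptor", el = "O"),
  "DA N6"   = list(role = "donor", el = "N", ctx = c("C6", "N1"), nn = 1),
  "DA N3"   = list(role = "acceptor", el = "N"),
  "DC N3"   = list(role = "acceptor", el = "N"),
  "DC O2"   = list(role = "acceptor", el = "O"))

.or_len <- function(v) sqrt(v[1]^2 + v[2]^2 + v[3]^2)

.or_angle <- function(u, v) {
  cc <- sum(u * v) / (.or_len(u) * .or_len(v))
  acos(min(1, max(-1, cc))) * 180 / pi
}

# Deviation-from-linearity angle of a donor donating toward acceptor A.
# Rotatable or context-less donors: 0 by the permissive convention.
.or_theta <- function(amat, i, A, info) {
  if (isTRUE(info$rot)) return(0)
  if (is.null(info$ctx)) return(0)
  res <- amat[amat$chain == amat$chain[i] & amat$resno == amat$resno[i], ]
  D <- c(amat$x[i], amat$y[i], amat$z[i])
  pget <- function(nm) {
    j <- which(res$name == nm)
    if (!length(j)) return(NULL)
    c(res$x[j[1]], res$y[j[1]], res$z[j[1]])
  }
  p1 <- pget(info$ctx[1]); p2 <- pget(info$ctx[2])
  if (is.null(p1) || is.null(p2)) return(0)
  if (info$nn == 2) {
    u1 <- (p1 - D) / .or_len(p1 - D)
    u2 <- (p2 - D) / .or_len(p2 - D)
    h <- -(u1 + u2)
    if (.or_len(h) < 1e-8) return(0)
    return(.or_angle(A - D, h))
  }
  u1 <- (p1 - D) / .or_len(p1 - D)
  w <- (p2 - D) - sum((p2 - D) * u1) * u1
  if (.or_len(w) < 1e-8) return(0)
  w <- w / .or_len(w)
  h1 <- cos(2 * pi / 3) * u1 + sin(2 * pi / 3) * w
  h2 <- cos(2 * pi / 3) * u1 - sin(2 * pi / 3) * w
  min(.or_angle(A - D, h1), .or_angle(A - D, h2))
}

.OR_EPS <- c("N-N" = 2.0, "N-O" = 2.8, "O-O" = 4.0)
.OR_DOPT <- c("N-N" = 3.2, "N-O" = 3.0, "O-O" = 2.8)

# Exhaustive-pair total energy, applying every printed rule independently:
# amino-acid vs nucleotide pairs only, < 3.5 A, no carbons, N/O/S
# donor-acceptor pairs, 10-12 potential x cos^4(theta), theta <= 90.
oracleScore <- function(model) {
  a <- atoms(model)
  tot <- 0
  prot <- which(a$kind == "protein")
  dna <- which(a$kind == "nucleotide")
  for (i in prot) {
    for (j in dna) {
      if (a$element[i] %in% c("C", "H") || a$element[j] %in% c("C", "H"))
        next
      P <- c(a$x[i], a$y[i], a$z[i]); B <- c(a$x[j], a$y[j], a$z[j])
      d <- .or_len(P - B)
      if (d >= 3.5) next
      ri <- .OR_ROLES[[paste(a$resname[i], a$name[i])]]
      rj <- .OR_ROLES[[paste(a$resname[j], a$name[j])]]
      if (is.null(ri) || is.null(rj)) next
      best <- NULL
      if (ri$role %in% c("donor", "both") && rj$role %in% c("acceptor", "both")) {
        th <- .or_theta(a, i, B, ri)
        if (th <= 90) {
          cls <- paste(sort(c(ri$el, rj$el)), collapse = "-")
          e <- .OR_EPS[[cls]] * (3 * (.OR_DOPT[[cls]] / d)^8 -
                                 4 * (.OR_DOPT[[cls]] / d)^6) *
               cos(th * pi / 180)^4
          best <- e
        }
      }
      if (rj$role %in% c("donor", "both") && ri$role %in% c("acceptor", "both")) {
        th <- .or_theta(a, j, P, rj)
        if (th <= 90) {
          cls <- paste(sort(c(ri$el, rj$el)), collapse = "-")
          e <- .OR_EPS[[cls]] * (3 * (.OR_DOPT[[cls]] / d)^8 -
                                 4 * (.OR_DOPT[[cls]] / d)^6) *
               cos(th * pi / 180)^4
          if (is.null(best) || e < best) best <- e
        }
      }
      if (!is.null(best)) tot <- tot + best
    }
  }
  tot
}
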