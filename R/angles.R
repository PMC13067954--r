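#' Wrap angles to the periodic backbone-dihedral domain
#'
#' Maps arbitrary angles in degrees onto the half-open interval (-180, 180],
#' the domain used throughout the package for backbone dihedrals.
#'
#' @param x Numeric vector of angles in degrees. `NA` values pass through.
#' @return Numeric vector of the same length with all finite values in
#'   (-180, 180].
#' @examples
#' wrap_angle(c(200, -190, 180, -180, 540))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

#' Torsion angle defined by four points
#'
#' Signed dihedral angle, in degrees, of the plane (p1, p2, p3) relative to
#' the plane (p2, p3, p4), following the IUPAC sign convention used for
#' protein backbone phi/psi/omega angles.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle (deg) at vertex b of the triangle a-b-c
bond_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Boltzmann constant in kcal/(mol K)
#'
#' Value used for all free-energy conversions so that Boltzmann-inverted
#' surfaces come out in kcal/mol.
#' @export
kB_kcal <- 0.0019872041
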