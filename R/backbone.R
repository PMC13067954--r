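#' Standard backbone covalent geometry
#'
#' Bundle of bond lengths, bond angles and the peptide-bond torsion used by
#' [build_backbone()]. Defaults are the standard protein backbone values
#' (Engh-Huber-style averages) with a trans peptide bond.
#'
#' @param b_n_ca N-CA bond length, Angstrom.
#' @param b_ca_c CA-C bond length, Angstrom.
#' @param b_c_n C-N (peptide) bond length, Angstrom.
#' @param ang_n_ca_c N-CA-C bond angle, degrees.
#' @param ang_ca_c_n CA-C-N bond angle, degrees.
#' @param ang_c_n_ca C-N-CA bond angle, degrees.
#' @param omega Peptide-bond dihedral CA-C-N-CA, degrees; 180 is trans.
#' @return Object of class `backbone_geometry`.
#' @export
backbone_geometry <- function(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                              ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                              ang_c_n_ca = 121.7, omega = 180) {
  lens <- c(b_n_ca = b_n_ca, b_ca_c = b_ca_c, b_c_n = b_c_n)
  angs <- c(ang_n_ca_c = ang_n_ca_c, ang_ca_c_n = ang_ca_c_n,
            ang_c_n_ca = ang_c_n_ca)
  if (any(lens <= 0)) stop("bond lengths must be positive")
  if (any(angs <= 0 | angs >= 180)) stop("bond angles must lie in (0, 180)")
  structure(list(lengths = lens, angles = angs, omega = omega),
            class = "backbone_geometry")
}

# Place atom D given three previous atoms and internal coordinates
# (natural-extension reference frame). r in Angstrom, theta/tau in degrees.
place_atom <- function(a, b, c, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  d_loc <- c(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  c + d_loc[1] * bc + d_loc[2] * m + d_loc[3] * n
}

#' Build idealised N/CA/C backbone coordinates from dihedral angles
#'
#' Constructs Cartesian backbone coordinates for a peptide chain by
#' sequential frame placement (natural-extension style), given per-residue
#' (phi, psi) torsions and a fixed covalent geometry. Only the three
#' backbone heavy atoms N, CA, C are built; side chains and glycans are
#' never represented in 3D (glycosylation is carried as annotation).
#'
#' The first residue's phi and the last residue's psi do not influence the
#' coordinates (they are undefined for a finite chain); they are recorded
#' as `NA` in the returned object rather than silently dropped.
#'
#' @param sequence One-letter amino-acid string, or an integer giving the
#'   chain length (sequence then defaults to poly-alanine).
#' @param phi,psi Numeric vectors of per-residue torsions in degrees, each
#'   either length 1 (recycled) or one per residue. `phi[1]` and
#'   `psi[n]` may be `NA`.
#' @param geometry A [backbone_geometry()].
#' @return Object of class `backbone_conformation`: list with `sequence`,
#'   `phi`, `psi` (degrees, termini `NA`), `coords` (array
#'   `n_res x 3 atoms x 3 xyz`, Angstrom) and `geometry`.
#' @examples
#' conf <- build_backbone(12, phi = -75, psi = 145)
#' backbone_dihedrals(conf)$phi[2]
#' @export
build_backbone <- function(sequence, phi, psi, geometry = backbone_geometry()) {
  if (is.numeric(sequence) && length(sequence) == 1) {
    sequence <- paste(rep("A", sequence), collapse = "")
  }
  n <- nchar(sequence)
  if (n < 2) stop("chain must have at least 2 residues")
  if (length(phi) == 1) phi <- rep(phi, n)
  if (length(psi) == 1) psi <- rep(psi, n)
  if (length(phi) != n || length(psi) != n)
    stop("phi and psi must have one value per residue")
  if (any(!is.finite(phi[-1])) || any(!is.finite(psi[-n])))
    stop("interior dihedral angles must be finite")
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)

  g <- geometry
  b <- g$lengths
  a <- g$angles
  xyz <- array(NA_real_, dim = c(n, 3, 3),
               dimnames = list(NULL, c("N", "CA", "C"), c("x", "y", "z")))
  # canonical placement of the first residue: N at origin, CA on +x,
  # C in the xy-plane
  xyz[1, "N", ] <- c(0, 0, 0)
  xyz[1, "CA", ] <- c(b["b_n_ca"], 0, 0)
  th <- a["ang_n_ca_c"] * pi / 180
  xyz[1, "C", ] <- xyz[1, "CA", ] +
    b["b_ca_c"] * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    xyz[i, "N", ] <- place_atom(xyz[i - 1, "N", ], xyz[i - 1, "CA", ],
                                xyz[i - 1, "C", ], b["b_c_n"],
                                a["ang_ca_c_n"], psi[i - 1])
    xyz[i, "CA", ] <- place_atom(xyz[i - 1, "CA", ], xyz[i - 1, "C", ],
                                 xyz[i, "N", ], b["b_n_ca"],
                                 a["ang_c_n_ca"], g$omega)
    xyz[i, "C", ] <- place_atom(xyz[i - 1, "C", ], xyz[i, "N", ],
                                xyz[i, "CA", ], b["b_ca_c"],
                                a["ang_n_ca_c"], phi[i])
  }
  phi[1] <- NA_real_
  psi[n] <- NA_real_
  structure(list(sequence = sequence, phi = phi, psi = psi,
                 coords = xyz, geometry = g),
            class = "backbone_conformation")
}

#' Recompute backbone dihedrals from Cartesian coordinates
#'
#' Extracts phi = C(i-1)-N(i)-CA(i)-C(i), psi = N(i)-CA(i)-C(i)-N(i+1) and
#' omega = CA(i)-C(i)-N(i+1)-CA(i+1) from an `n_res x 3 x 3` coordinate
#' array. Terminal angles without a defining atom are `NA`.
#'
#' @param x A `backbone_conformation` or a coordinate array of dimension
#'   `n_res x 3 (N, CA, C) x 3 (x, y, z)`.
#' @return List with numeric vectors `phi`, `psi`, `omega` (degrees).
#' @export
backbone_dihedrals <- function(x) {
  xyz <- if (inherits(x, "backbone_conformation")) x$coords else x
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  n <- dim(xyz)[1]
  phi <- psi <- omg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- dihedral_angle(xyz[i - 1, "C", ], xyz[i, "N", ],
                               xyz[i, "CA", ], xyz[i, "C", ])
    }
    if (i < n) {
      psi[i] <- dihedral_angle(xyz[i, "N", ], xyz[i, "CA", ],
                               xyz[i, "C", ], xyz[i + 1, "N", ])
      omg[i] <- dihedral_angle(xyz[i, "CA", ], xyz[i, "C", ],
                               xyz[i + 1, "N", ], xyz[i + 1, "CA", ])
    }
  }
  list(phi = phi, psi = psi, omega = omg)
}

#' @export
print.backbone_conformation <- function(x, ...) {
  cat("Backbone conformation:", nchar(x$sequence), "residues\n")
  cat("  sequence:", x$sequence, "\n")
  ph <- stats::na.omit(x$phi); ps <- stats::na.omit(x$psi)
  if (max(ph) - min(ph) < 1e-9 && max(ps) - min(ps) < 1e-9) {
    cat(sprintf("  uniform (phi, psi) = (%.1f, %.1f) deg\n", ph[1], ps[1]))
  }
  invisible(x)
}

#' Helical parameters of a uniform backbone conformation
#'
#' Treats the repeating residue-to-residue rigid transform of a uniform
#' chain (all residues sharing the same (phi, psi)) as a screw motion and
#' reports its twist, rise and handedness. The transform is obtained by
#' least-squares superposition of each residue's N/CA/C triad onto the
#' next; for an ideal uniform chain all consecutive transforms agree.
#'
#' Handedness follows the usual convention: looking along the direction of
#' helix advance, a right-handed helix twists by the right-hand rule
#' (positive screw angle). The canonical PPII conformation
#' (phi, psi) = (-75, 145) gives a left-handed helix with about 3 residues
#' per turn; the alpha-helical (-57, -47) gives a right-handed helix with
#' about 3.6.
#'
#' @param conf A `backbone_conformation` with at least 6 residues, uniform
#'   in (phi, psi) (tolerance `tol` degrees).
#' @param tol Uniformity tolerance in degrees.
#' @return Object of class `helix_parameters`: list with
#'   `residues_per_turn`, `rise_per_residue` (Angstrom), `twist_per_residue`
#'   (signed degrees) and `handedness` (`"left"` or `"right"`).
#' @examples
#' helix_parameters(build_backbone(12, -75, 145))
#' @export
helix_parameters <- function(conf, tol = 1e-6) {
  stopifnot(inherits(conf, "backbone_conformation"))
  n <- dim(conf$coords)[1]
  if (n < 6) stop("helix fitting requires at least 6 residues")
  ph <- conf$phi[-1]; ps <- conf$psi[-n]
  if (max(ph) - min(ph) > tol || max(ps) - min(ps) > tol)
    stop("chain is not uniform in (phi, psi); helix parameters undefined")

  twists <- numeric(n - 1)
  rises <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    fit <- rigid_transform(conf$coords[i, , ], conf$coords[i + 1, , ])
    sc <- screw_decompose(fit$R, fit$t)
    twists[i] <- sc$angle
    rises[i] <- sc$rise
  }
  twist <- mean(twists)
  structure(list(residues_per_turn = 360 / abs(twist),
                 rise_per_residue = mean(rises),
                 twist_per_residue = twist,
                 handedness = if (twist > 0) "right" else "left"),
            class = "helix_parameters")
}

#' @export
print.helix_parameters <- function(x, ...) {
  cat(sprintf("%s-handed helix: %.3f residues/turn, rise %.3f A/residue\n",
              x$handedness, x$residues_per_turn, x$rise_per_residue))
  invisible(x)
}

# Least-squares rigid transform mapping point set X (rows) onto Y (Kabsch).
rigid_transform <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cy - as.vector(R %*% cx))
}

# Screw decomposition of x -> R x + t: signed rotation angle (deg) about the
# axis oriented along the translation (direction of advance), plus the rise.
screw_decompose <- function(R, t) {
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(v^2)) / 2         # |sin(angle)|, axis = v / (2 sin)
  ctr <- (sum(diag(R)) - 1) / 2
  if (s < 1e-12) return(list(angle = 0, rise = sqrt(sum(t^2))))
  u <- v / (2 * s)
  ang <- atan2(s, ctr) * 180 / pi # in (0, 180), rotation about u
  rise <- sum(u * t)
  if (rise < 0) {                 # orient axis along advance
    u <- -u; ang <- -ang; rise <- -rise
  }
  list(angle = ang, rise = rise, axis = u)
}
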