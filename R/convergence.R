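#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of atoms from their center of
#' mass, `Rg = sqrt( (1/M) * sum_i m_i * |r_i - R|^2 )` — the standard
#' compactness measure used for sampling-convergence checks. Accepts a
#' single frame (atoms x 3 matrix or a `backbone_conformation`) or a
#' trajectory (frames x atoms x 3 array), with equal masses by default.
#'
#' @param x Coordinates in Angstrom: `atoms x 3` matrix, `frames x atoms
#'   x 3` array, or a `backbone_conformation`.
#' @param masses Optional positive per-atom masses; equal masses when
#'   omitted (appropriate for idealised N/CA/C backbones).
#' @return Numeric Rg per frame, Angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # two masses: d/2
#' @export
radius_of_gyration <- function(x, masses = NULL) {
  if (inherits(x, "backbone_conformation")) {
    n <- dim(x$coords)[1]
    x <- matrix(aperm(x$coords, c(2, 1, 3)), ncol = 3)
  }
  one <- function(m) {
    if (is.null(masses)) masses <- rep(1, nrow(m))
    if (length(masses) != nrow(m)) stop("one mass per atom required")
    if (any(masses <= 0)) stop("masses must be positive")
    M <- sum(masses)
    ctr <- colSums(m * masses) / M
    sqrt(sum(masses * rowSums(sweep(m, 2, ctr)^2)) / M)
  }
  if (is.matrix(x)) return(one(x))
  stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
  vapply(seq_len(dim(x)[1]), function(f) one(x[f, , ]), numeric(1))
}

#' Per-frame backbone radius of gyration of a dihedral ensemble
#'
#' Rebuilds the idealised N/CA/C backbone of every frame from its
#' (phi, psi) angles and computes the equal-mass radius of gyration.
#' Frames with undefined terminal angles use the conventional PPII values
#' for the two torsions that do not affect relative atom positions only
#' through missing terminal atoms (phi of residue 1 and psi of the last
#' residue do not change the built coordinates).
#'
#' @param series A [dihedral_series()].
#' @param geometry A [backbone_geometry()].
#' @return Numeric vector, one Rg (Angstrom) per frame.
#' @export
trajectory_rg <- function(series, geometry = backbone_geometry()) {
  stopifnot(inherits(series, "dihedral_series"))
  phi <- series$phi; psi <- series$psi
  n <- ncol(phi)
  if (n < 2) stop("need at least 2 residues to build a backbone")
  phi[, 1][is.na(phi[, 1])] <- -75   # inert: does not move any atom
  psi[, n][is.na(psi[, n])] <- 145
  if (anyNA(phi) || anyNA(psi))
    stop("interior angles must be defined to rebuild coordinates")
  cpp_backbone_rg(phi, psi, unname(geometry$lengths),
                  unname(geometry$angles), geometry$omega)
}

#' Split a series into two equal contiguous halves
#'
#' The standard convergence protocol compares a property's distribution
#' over two successive halves of the analysis window (e.g. 100-150 ns
#' versus 150-200 ns of a 200-ns run analysed from 100 ns). For an odd
#' number of frames the first half receives the smaller count.
#'
#' @param x Numeric vector (e.g. per-frame Rg).
#' @return List with numeric vectors `a` (first half) and `b` (second).
#' @export
split_halves <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 frames to split into halves")
  h <- n %/% 2
  list(a = x[seq_len(h)], b = x[(h + 1):n])
}

#' Histogram overlap coefficient of two samples
#'
#' Builds histograms of both samples on shared bin edges spanning their
#' combined range and returns the overlap coefficient
#' `sum(pmin(p, q))` of the two normalised histograms: 1 for identical
#' distributions, 0 for disjoint supports.
#'
#' @param a,b Non-empty numeric samples.
#' @param n_bins Number of shared bins (default 50).
#' @return Object of class `overlap_report`: list with `coefficient`,
#'   `edges`, `p`, `q`, `n_bins`.
#' @export
histogram_overlap <- function(a, b, n_bins = 50) {
  stopifnot(length(a) > 0, length(b) > 0, n_bins >= 1)
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # all values identical
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  binit <- function(x) {
    i <- pmin(n_bins, pmax(1L, ceiling((x - rng[1]) / diff(rng) * n_bins)))
    tabulate(i, nbins = n_bins) / length(x)
  }
  p <- binit(a); q <- binit(b)
  structure(list(coefficient = sum(pmin(p, q)), edges = edges,
                 p = p, q = q, n_bins = n_bins),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Histogram overlap: %.1f%% over %d shared bins\n",
              100 * x$coefficient, x$n_bins))
  invisible(x)
}

#' Convergence verdict from a histogram-overlap report
#'
#' Declares sampling converged when the overlap coefficient between the
#' two half-window distributions reaches the threshold; the conventional
#' criterion is > 90 percent overlap, implemented inclusively (a
#' coefficient exactly at the threshold passes).
#'
#' @param report An `overlap_report`, or a bare overlap coefficient.
#' @param threshold Pass threshold on the overlap coefficient.
#' @return Logical verdict with attribute `coefficient`.
#' @export
convergence_check <- function(report, threshold = 0.90) {
  coef <- if (inherits(report, "overlap_report")) report$coefficient
          else as.numeric(report)
  structure(coef >= threshold, coefficient = coef, threshold = threshold)
}

#' Radius-of-gyration convergence diagnostic for a trajectory
#'
#' Convenience wrapper running the full protocol on a dihedral series:
#' per-frame backbone Rg, split of the analysis window into two equal
#' halves, 50-bin shared-edge histogram overlap, and the threshold
#' verdict.
#'
#' @param series A [dihedral_series()] (post-burn-in analysis window).
#' @param n_bins Histogram bins.
#' @param threshold Overlap pass threshold.
#' @param geometry A [backbone_geometry()].
#' @return List with `rg` (per-frame Rg), `overlap` (an
#'   `overlap_report`) and `converged` (verdict).
#' @export
rg_convergence <- function(series, n_bins = 50, threshold = 0.90,
                           geometry = backbone_geometry()) {
  rg <- trajectory_rg(series, geometry)
  halves <- split_halves(rg)
  ov <- histogram_overlap(halves$a, halves$b, n_bins)
  list(rg = rg, overlap = ov, converged = convergence_check(ov, threshold))
}
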