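#' Synthetic dihedral-ensemble generator specification
#'
#' Defines a generator of (phi, psi) ensembles with known ground truth:
#' each residue follows a sticky Markov chain over conformational basins
#' (stationary distribution equal to the basin weights, lag-1 stickiness
#' `rho`), and angles are drawn around the basin center with von Mises
#' concentration `kappa` (coil draws uniformly on the torus). This
#' emulates the 300 K output of a converged simulation — basin
#' occupancies, angular spread and temporal autocorrelation — without any
#' molecular dynamics.
#'
#' @param weights Basin weights over
#'   `c("PPII", "alpha_R", "beta", "alpha_L", "coil")`: a named vector
#'   shared by all residues, or a residues x 5 matrix of per-residue
#'   weights. Normalised internally.
#' @param n_frames Number of frames to generate.
#' @param n_residues Number of residues (ignored when `weights` is a
#'   matrix or `peptide` is given).
#' @param kappa Angular concentration of the basin bells.
#' @param rho Lag-1 autocorrelation (stickiness) of the basin-label
#'   chain, in [0, 1).
#' @param peptide Optional [peptide_spec()] supplying residue count and
#'   numbering.
#' @param seed Integer seed.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(weights = c(PPII = 0.55, alpha_R = 0.15,
                                       beta = 0.2, alpha_L = 0.03,
                                       coil = 0.07),
                           n_frames = 1000, n_residues = 1, kappa = 8,
                           rho = 0.9, peptide = NULL, seed = 1L) {
  lev <- c("PPII", "alpha_R", "beta", "alpha_L", "coil")
  if (!is.matrix(weights)) {
    stopifnot(all(lev %in% names(weights)))
    nr <- if (!is.null(peptide)) nchar(peptide$sequence) else n_residues
    weights <- matrix(rep(as.numeric(weights[lev]), each = nr), nrow = nr,
                      dimnames = list(NULL, lev))
  } else {
    stopifnot(identical(colnames(weights), lev))
    if (!is.null(peptide)) stopifnot(nrow(weights) == nchar(peptide$sequence))
  }
  if (any(weights < 0) || any(rowSums(weights) <= 0))
    stop("basin weights must be nonnegative with positive row sums")
  weights <- weights / rowSums(weights)
  stopifnot(rho >= 0, rho < 1, kappa > 0, n_frames >= 1)
  structure(list(weights = weights, n_frames = as.integer(n_frames),
                 kappa = kappa, rho = rho, peptide = peptide,
                 seed = as.integer(seed), basin_levels = lev),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("Ensemble generator: %d frames x %d residues, kappa = %g, rho = %g\n",
              x$n_frames, nrow(x$weights), x$kappa, x$rho))
  invisible(x)
}

# von Mises sampler (Best & Fisher rejection scheme), vectorised over n;
# returns degrees around a center given in degrees.
rvonmises_deg <- function(n, center, kappa) {
  if (n == 0) return(numeric())
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
    out[need[ok]] <- theta[ok]
    need <- need[!ok]
  }
  wrap_angle(center + out * 180 / pi)
}

# sticky Markov chain over 1..k with stationary distribution pi and
# stay-probability rho: with prob rho keep the previous label, otherwise
# redraw from pi. Vectorised via last-observation-carried-forward.
sticky_chain <- function(n, pi, rho) {
  draws <- sample.int(length(pi), n, replace = TRUE, prob = pi)
  if (rho == 0 || n == 1) return(draws)
  redraw <- c(TRUE, stats::runif(n - 1) >= rho)
  src <- cummax(seq_len(n) * redraw)   # index of last redraw
  draws[src]
}

#' Sample a synthetic dihedral ensemble with known ground truth
#'
#' Draws per-residue basin-label chains and angles according to a
#' [generator_spec()]. Residue chains are independent of each other;
#' within a residue, labels have lag-1 autocorrelation `rho` and
#' stationary distribution equal to the (normalised) basin weights.
#' Basin centers are those of [ramachandran_basins()]; coil is uniform
#' on the torus, its classification decided downstream by
#' [classify_region()].
#'
#' @param spec A [generator_spec()].
#' @return List with `series` (a [dihedral_series()]) and `labels`
#'   (frames x residues factor-coded integer matrix of true basin
#'   labels, levels `spec$basin_levels`).
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames
  nr <- nrow(spec$weights)
  centers <- ramachandran_basins()
  phi <- psi <- matrix(NA_real_, nf, nr)
  labels <- matrix(NA_integer_, nf, nr)
  for (j in seq_len(nr)) {
    lab <- sticky_chain(nf, spec$weights[j, ], spec$rho)
    labels[, j] <- lab
    for (k in 1:4) {
      idx <- which(lab == k)
      if (!length(idx)) next
      phi[idx, j] <- rvonmises_deg(length(idx), centers$phi0[k], spec$kappa)
      psi[idx, j] <- rvonmises_deg(length(idx), centers$psi0[k], spec$kappa)
    }
    idx <- which(lab == 5L)   # coil: uniform on the torus
    if (length(idx)) {
      phi[idx, j] <- stats::runif(length(idx), -180, 180)
      psi[idx, j] <- stats::runif(length(idx), -180, 180)
    }
  }
  rn <- if (!is.null(spec$peptide)) spec$peptide$residue_numbers
        else seq_len(nr)
  list(series = dihedral_series(phi, psi, residue_numbers = rn,
                                temperature = 300,
                                source = sprintf("synthetic seed %d",
                                                 spec$seed)),
       labels = labels)
}

#' Paired glycosylated / nonglycosylated synthetic ensembles
#'
#' Generates two ensembles from the same base generator, differing only
#' at glycosylated threonines (and, when `cooperative`, at
#' nonglycosylated threonines directly adjacent to a glycosylated one),
#' where the glycosylation effect suppresses the right-handed alpha
#' basin and transfers the removed weight to PPII — the population shift
#' O-linked GalNAc-Gal glycans impose on threonines. Both ensembles use
#' the seed of `base`, enabling paired testing.
#'
#' @param base A [generator_spec()] whose `peptide` is set and carries
#'   `glyco_sites`.
#' @param alpha_factor Multiplier (near 0) on the alpha_R weight of
#'   affected residues; the removed weight moves to PPII.
#' @param cooperative Logical; extend the effect to nonglycosylated
#'   threonines adjacent in sequence to a glycosylated threonine,
#'   mirroring the cooperativity seen for the unglycosylated threonine
#'   of the mucin repeat variant.
#' @return List with `nonglyco` and `glyco`, each as returned by
#'   [sample_ensemble()], plus `affected_residues` (residue numbers whose
#'   generator weights differ).
#' @export
paired_glyco_ensembles <- function(base, alpha_factor = 0.02,
                                   cooperative = TRUE) {
  stopifnot(inherits(base, "generator_spec"), !is.null(base$peptide))
  pep <- base$peptide
  affected <- pep$glyco_sites
  if (cooperative && length(affected)) {
    aa <- residue_letters(pep$sequence)
    thr <- pep$residue_numbers[aa == "T"]
    extra <- thr[!thr %in% affected &
                   ((thr - 1L) %in% affected | (thr + 1L) %in% affected)]
    affected <- sort(unique(c(affected, extra)))
  }
  glyco <- base
  if (length(affected) && alpha_factor != 1) {
    idx <- match(affected, pep$residue_numbers)
    moved <- glyco$weights[idx, "alpha_R"] * (1 - alpha_factor)
    glyco$weights[idx, "alpha_R"] <- glyco$weights[idx, "alpha_R"] - moved
    glyco$weights[idx, "PPII"] <- glyco$weights[idx, "PPII"] + moved
  }
  list(nonglyco = sample_ensemble(base),
       glyco = sample_ensemble(glyco),
       affected_residues = if (alpha_factor == 1) integer() else affected)
}
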