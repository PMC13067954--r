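#' Default Ramachandran basin table
#'
#' The four canonical secondary-structure basins used by the torsional
#' potential and the synthetic-ensemble generator. Centers sit inside the
#' corresponding classification regions (see [region_spec()]) so that
#' basin occupancy is unambiguous at moderate angular concentration:
#' PPII (-75, 145), right-handed alpha (-60, -45), beta (-135, 135) and
#' left-handed alpha (60, 45).
#'
#' The default weights make PPII the global minimum with the competing
#' basins 1-2.4 kcal/mol above it at unit depth scale, the ordering
#' expected for a proline-rich mucin repeat.
#'
#' @param weights Named numeric basin weights (any positive scale).
#' @param kappa Angular concentration (dimensionless), shared by default.
#' @return Data frame with columns `name`, `phi0`, `psi0`, `kappa`,
#'   `weight`.
#' @export
ramachandran_basins <- function(weights = c(PPII = 1, alpha_R = 0.22,
                                            beta = 0.35, alpha_L = 0.1),
                                kappa = 8) {
  nm <- c("PPII", "alpha_R", "beta", "alpha_L")
  stopifnot(all(nm %in% names(weights)), all(weights > 0))
  data.frame(name = nm,
             phi0 = c(-75, -60, -135, 60),
             psi0 = c(145, -45, 135, 45),
             kappa = rep_len(kappa, 4),
             weight = as.numeric(weights[nm]))
}

#' Basin-mixture torsional potential for a peptide
#'
#' A smooth per-residue potential on the Ramachandran torus,
#' \deqn{U(\phi,\psi) = -\epsilon \log \sum_k w_k\,
#'   e^{\kappa_k(\cos(\phi-\phi_{0k})-1)}\, e^{\kappa_k(\cos(\psi-\psi_{0k})-1)},}
#' a log-sum of von Mises-type bells centred on the secondary-structure
#' basins. Residues are energetically independent; the total energy of a
#' chain is the sum of per-residue terms.
#'
#' O-linked glycosylation is modelled as a weight modifier: for residues
#' listed as glycosylation sites in the peptide spec, the right-handed
#' alpha basin weight is multiplied by `glyco_alpha_factor` and the
#' removed weight is transferred to the PPII basin, reflecting the steric
#' destabilisation of the compact alpha conformation by the bulky
#' GalNAc-Gal glycan.
#'
#' @param spec A [peptide_spec()], or an integer residue count (no
#'   glycosylation).
#' @param basins Basin table from [ramachandran_basins()].
#' @param epsilon Depth scale in kcal/mol.
#' @param glyco_alpha_factor Multiplier (< 1) on the alpha_R weight of
#'   glycosylated residues.
#' @return Object of class `torsion_potential`: basin centers, kappas,
#'   per-residue weight matrix, `epsilon` and the originating spec.
#' @examples
#' pot <- torsion_potential(lubricin_model_peptide())
#' potential_energy(pot, phi = -75, psi = 145)
#' @export
torsion_potential <- function(spec, basins = ramachandran_basins(),
                              epsilon = 1, glyco_alpha_factor = 0.05) {
  if (is.numeric(spec) && length(spec) == 1) {
    spec <- peptide_spec(paste(rep("A", spec), collapse = ""))
  }
  stopifnot(inherits(spec, "peptide_spec"), epsilon > 0,
            glyco_alpha_factor > 0)
  n <- nchar(spec$sequence)
  w <- matrix(rep(basins$weight, each = n), nrow = n,
              dimnames = list(NULL, basins$name))
  if (length(spec$glyco_sites)) {
    idx <- match(spec$glyco_sites, spec$residue_numbers)
    moved <- w[idx, "alpha_R"] * (1 - glyco_alpha_factor)
    w[idx, "alpha_R"] <- w[idx, "alpha_R"] - moved
    w[idx, "PPII"] <- w[idx, "PPII"] + moved
  }
  structure(list(spec = spec,
                 centers = as.matrix(basins[, c("phi0", "psi0")]),
                 kappa = basins$kappa,
                 epsilon = epsilon,
                 weights = w,
                 glyco_alpha_factor = glyco_alpha_factor),
            class = "torsion_potential")
}

#' @export
print.torsion_potential <- function(x, ...) {
  cat(sprintf("Torsional basin potential: %d residues, %d basins, epsilon = %g kcal/mol\n",
              nrow(x$weights), nrow(x$centers), x$epsilon))
  if (length(x$spec$glyco_sites))
    cat(sprintf("  glycosylated residues (alpha_R weight x %g): %s\n",
                x$glyco_alpha_factor,
                paste(x$spec$glyco_sites, collapse = ", ")))
  invisible(x)
}

#' Evaluate the torsional potential
#'
#' @param potential A [torsion_potential()].
#' @param phi,psi Angles in degrees: either one value per residue (a
#'   single chain state) or a single pair evaluated for residue `residue`.
#' @param residue Residue index used when `phi`/`psi` are scalars.
#' @param total Logical; sum per-residue energies into a chain energy.
#' @return Energy in kcal/mol (vector of per-residue energies, or scalar
#'   if `total`).
#' @export
potential_energy <- function(potential, phi, psi, residue = NULL,
                             total = FALSE) {
  stopifnot(inherits(potential, "torsion_potential"))
  n <- nrow(potential$weights)
  if (!is.null(residue)) {
    stopifnot(length(phi) == length(psi))
    idx <- if (length(residue) == 1) rep(residue, length(phi)) else residue
    stopifnot(length(idx) == length(phi))
    w <- potential$weights[idx, , drop = FALSE]
    e <- cpp_residue_energies(phi, psi, w, potential$centers,
                              potential$kappa, potential$epsilon)
    return(e)
  }
  stopifnot(length(phi) == n, length(psi) == n)
  e <- cpp_residue_energies(phi, psi, potential$weights, potential$centers,
                            potential$kappa, potential$epsilon)
  if (total) sum(e) else e
}

#' Geometric replica temperature ladder
#'
#' Temperatures in geometric progression, `T_i = T_min * r^(i-1)` with
#' `r = (T_max/T_min)^(1/(n-1))`, so that the ratio of neighbouring
#' temperatures (and hence the expected exchange acceptance) is constant
#' along the ladder. Defaults mirror a 64-replica ladder from 300 K to
#' 455.95 K.
#'
#' @param t_min,t_max Endpoint temperatures in kelvin.
#' @param n_replicas Number of replicas (>= 2).
#' @return Object of class `replica_ladder` (numeric temperature vector).
#' @examples
#' make_ladder(300, 455.95, 64)[c(1, 64)]
#' @export
make_ladder <- function(t_min = 300, t_max = 455.95, n_replicas = 64) {
  if (n_replicas < 2) stop("a replica ladder needs at least 2 replicas")
  if (!(t_max > t_min) || t_min <= 0)
    stop("temperatures must satisfy 0 < t_min < t_max")
  r <- (t_max / t_min)^(1 / (n_replicas - 1))
  temps <- t_min * r^(seq_len(n_replicas) - 1)
  temps[n_replicas] <- t_max   # endpoint exact despite rounding
  structure(temps, class = "replica_ladder", ratio = r)
}

#' @export
print.replica_ladder <- function(x, ...) {
  cat(sprintf("Geometric replica ladder: %d temperatures, %.2f-%.2f K (ratio %.5f)\n",
              length(x), x[1], x[length(x)], attr(x, "ratio")))
  invisible(x)
}
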