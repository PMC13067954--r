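#' Monte Carlo run configuration
#'
#' Settings for [run_remd()] and [mc_sweep()]. A "sweep" proposes one
#' move of every phi and psi angle in the chain; exchange attempts
#' between neighbouring temperature replicas are made every
#' `exchange_every` sweeps, and the state is recorded every
#' `record_every` sweeps. The first `burn_in` fraction of recorded frames
#' is discarded before analysis, mirroring the usual practice of
#' analysing only the converged second half of a trajectory.
#'
#' @param sweeps Total number of sweeps.
#' @param step Maximum proposal perturbation per angle, degrees; the
#'   default 60 keeps single-angle Metropolis acceptance moderate while
#'   still allowing basin-to-basin hops within a sweep.
#' @param exchange_every Sweeps between exchange attempts.
#' @param record_every Sweeps between recorded frames.
#' @param burn_in Fraction of recorded frames discarded from the start.
#' @param seed Integer seed driving the whole run.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(sweeps = 2e5, step = 60, exchange_every = 10,
                      record_every = 10, burn_in = 0.5, seed = 1L) {
  stopifnot(sweeps >= 1, step >= 0, exchange_every >= 1, record_every >= 1,
            burn_in >= 0, burn_in < 1)
  structure(list(sweeps = as.integer(sweeps), step = step,
                 exchange_every = as.integer(exchange_every),
                 record_every = as.integer(record_every),
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "mc_config")
}

#' Single Metropolis sweep over a chain state
#'
#' Proposes, residue by residue, a uniform perturbation of +/- `step`
#' degrees first of phi then of psi, accepting each with the Metropolis
#' probability `min(1, exp(-dU / (kB T)))`. Uses R's global RNG stream.
#'
#' @param state List with numeric vectors `phi` and `psi` (degrees, one
#'   per residue).
#' @param potential A [torsion_potential()].
#' @param temperature Temperature in kelvin.
#' @param step Maximum perturbation in degrees.
#' @param n_sweeps Number of consecutive sweeps to apply.
#' @return Updated state list with elements `phi`, `psi` and `energy`
#'   (total chain energy, kcal/mol).
#' @export
mc_sweep <- function(state, potential, temperature, step = 60,
                     n_sweeps = 1) {
  stopifnot(inherits(potential, "torsion_potential"), temperature > 0)
  n <- nrow(potential$weights)
  stopifnot(length(state$phi) == n, length(state$psi) == n)
  res <- cpp_remd(potential$weights, potential$centers, potential$kappa,
                  potential$epsilon, temperature,
                  matrix(state$phi, nrow = 1), matrix(state$psi, nrow = 1),
                  as.integer(n_sweeps), step, 0L, 0L, kB_kcal)
  list(phi = as.vector(res$final_phi), psi = as.vector(res$final_psi),
       energy = sum(potential_energy(potential, as.vector(res$final_phi),
                                     as.vector(res$final_psi))))
}

#' Replica-exchange acceptance rule
#'
#' Standard parallel-tempering Metropolis criterion: a swap between the
#' configurations at temperatures `t_i` and `t_j` with energies `e_i`,
#' `e_j` is accepted with probability
#' `min(1, exp((1/(kB t_i) - 1/(kB t_j)) * (e_i - e_j)))`.
#'
#' @param e_i,e_j Energies in kcal/mol.
#' @param t_i,t_j Temperatures in kelvin.
#' @param draw Logical; if `TRUE`, draw from R's RNG and return whether
#'   the swap is accepted; if `FALSE`, return the acceptance probability.
#' @return Acceptance probability, or a logical swap decision.
#' @examples
#' exchange_attempt(10, 10, 300, 320)          # equal energies: 1
#' @export
exchange_attempt <- function(e_i, e_j, t_i, t_j, draw = FALSE) {
  p <- min(1, exp((1 / (kB_kcal * t_i) - 1 / (kB_kcal * t_j)) * (e_i - e_j)))
  if (draw) stats::runif(1) < p else p
}

#' Replica-exchange torsional Monte Carlo run
#'
#' Runs parallel Metropolis sampling of the per-residue (phi, psi)
#' torsions at every temperature of a geometric ladder, with periodic
#' exchange attempts between neighbouring replicas (odd/even pair
#' alternation) under the standard parallel-tempering criterion. All
#' replicas start from the PPII conformation (-75, 145), the expected
#' dominant conformation of mucin repeats.
#'
#' Recorded trajectories are per *temperature*: at each exchange the
#' configurations are swapped between temperature slots, so the series
#' returned for a temperature always contains the configuration currently
#' simulated at that temperature. The multiset of configurations across
#' temperatures is conserved by swaps.
#'
#' @param potential A [torsion_potential()] (or a [peptide_spec()], from
#'   which a default potential is built).
#' @param ladder A [make_ladder()] temperature ladder (or a single
#'   temperature for plain Metropolis sampling).
#' @param config An [mc_config()].
#' @param init Optional list with `phi`, `psi` initial angles (one per
#'   residue, recycled across replicas).
#' @return Object of class `replica_run`: list with `series` (list of
#'   post-burn-in [dihedral_series()], one per temperature), `energy`
#'   (post-burn-in frames x temperatures matrix, kcal/mol),
#'   `exchange_rates` (acceptance fraction per neighbouring pair),
#'   `ladder`, `config`, `potential`.
#' @examples
#' \donttest{
#' pot <- torsion_potential(threonine_tetrapeptide(FALSE))
#' run <- run_remd(pot, make_ladder(300, 452.32, 4),
#'                 mc_config(sweeps = 2000, seed = 7))
#' run$exchange_rates
#' }
#' @export
run_remd <- function(potential, ladder = make_ladder(),
                     config = mc_config(), init = NULL) {
  if (inherits(potential, "peptide_spec"))
    potential <- torsion_potential(potential)
  stopifnot(inherits(potential, "torsion_potential"))
  temps <- as.numeric(ladder)
  K <- length(temps)
  n <- nrow(potential$weights)
  if (is.null(init)) init <- list(phi = rep(-75, n), psi = rep(145, n))
  if (is.matrix(init$phi)) {
    stopifnot(all(dim(init$phi) == c(K, n)), all(dim(init$psi) == c(K, n)))
    phi0 <- init$phi; psi0 <- init$psi
  } else {
    phi0 <- matrix(rep_len(init$phi, n), nrow = K, ncol = n, byrow = TRUE)
    psi0 <- matrix(rep_len(init$psi, n), nrow = K, ncol = n, byrow = TRUE)
  }

  set.seed(config$seed)
  raw <- cpp_remd(potential$weights, potential$centers, potential$kappa,
                  potential$epsilon, temps, phi0, psi0,
                  config$sweeps, config$step, config$exchange_every,
                  config$record_every, kB_kcal)
  nrec <- config$sweeps %/% config$record_every
  keep <- seq.int(floor(config$burn_in * nrec) + 1, nrec)
  phi <- array(raw$phi, dim = c(nrec, K, n))
  psi <- array(raw$psi, dim = c(nrec, K, n))
  series <- lapply(seq_len(K), function(k) {
    dihedral_series(matrix(phi[keep, k, ], nrow = length(keep), ncol = n),
                    matrix(psi[keep, k, ], nrow = length(keep), ncol = n),
                    residue_numbers = potential$spec$residue_numbers,
                    temperature = temps[k],
                    source = sprintf("toy-REMD seed %d", config$seed))
  })
  rates <- if (K > 1) raw$exchange_accepts / pmax(1, raw$exchange_attempts)
           else numeric()
  structure(list(series = series, energy = raw$energy[keep, , drop = FALSE],
                 exchange_rates = rates, ladder = temps, config = config,
                 potential = potential),
            class = "replica_run")
}

#' @export
print.replica_run <- function(x, ...) {
  cat(sprintf("Replica-exchange MC run: %d replicas (%.1f-%.1f K), %d post-burn-in frames\n",
              length(x$ladder), min(x$ladder), max(x$ladder),
              nrow(x$energy)))
  if (length(x$exchange_rates))
    cat(sprintf("  exchange acceptance: %.2f-%.2f\n",
                min(x$exchange_rates), max(x$exchange_rates)))
  invisible(x)
}

#' Extract the trajectory at a given temperature
#'
#' @param run A `replica_run`.
#' @param temperature Temperature in kelvin; defaults to the coldest
#'   replica (the analysis temperature).
#' @return A [dihedral_series()].
#' @export
cold_series <- function(run, temperature = NULL) {
  stopifnot(inherits(run, "replica_run"))
  if (is.null(temperature)) return(run$series[[1]])
  k <- which.min(abs(run$ladder - temperature))
  run$series[[k]]
}
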