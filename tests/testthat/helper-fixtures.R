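# shared fixtures and independent oracles for the test suite

# single-basin PPII-only potential for Boltzmann-recovery checks
single_basin_potential <- function(n_res = 1, kappa = 8) {
  b <- ramachandran_basins(kappa = kappa)
  pot <- torsion_potential(n_res, basins = b)
  pot$weights[, c("alpha_R", "beta", "alpha_L")] <- 0
  pot
}

# Boltzmann distribution of one residue of a potential on a bins x bins
# grid over the torus (independent quadrature oracle for the sampler)
grid_boltzmann <- function(pot, temperature, bins = 72, residue = 1) {
  w <- 360 / bins
  g <- seq(-180 + w / 2, 180 - w / 2, by = w)
  U <- outer(g, g, function(p, q)
    potential_energy(pot, p, q, residue = rep(residue, length(p))))
  P <- exp(-U / (kB_kcal * temperature))
  P / sum(P)
}

# independent implementation of the printed region bounds, scalar, used
# as the brute-force classification oracle (including the +360 psi lift)
oracle_region <- function(phi, psi) {
  lifted <- function(psi, hi) if (hi > 180 && psi < hi - 360) psi + 360 else psi
  if (phi > -160 && phi < -20 && psi > -120 && psi < 50) return("alpha_R")
  p <- lifted(psi, 240)
  if (phi > -180 && phi < -90 && p > 50 && p < 240) return("beta")
  if (phi > -90 && phi < 20 && p > 50 && p < 240) return("PPII")
  if (phi > 30 && phi < 100 && psi > 0 && psi < 80) return("alpha_L")
  "coil"
}

# basin -> region confusion matrix of the synthetic generator at a given
# concentration, by 1-degree quadrature of the von Mises product density;
# rows: PPII, alpha_R, beta, alpha_L, coil; columns: classifier labels
generator_confusion <- function(kappa, grid_step = 1) {
  g <- seq(-180 + grid_step / 2, 180 - grid_step / 2, by = grid_step)
  vm <- function(mu) { d <- exp(kappa * cos((g - mu) * pi / 180)); d / sum(d) }
  bas <- ramachandran_basins()
  lab <- classify_region(rep(g, times = length(g)), rep(g, each = length(g)))
  lev <- levels(lab)
  M <- matrix(0, 5, length(lev), dimnames = list(c(bas$name, "coil"), lev))
  for (k in 1:4) {
    dens <- outer(vm(bas$phi0[k]), vm(bas$psi0[k]))
    for (r in lev)
      M[k, r] <- sum(dens[matrix(lab == r, length(g), length(g))])
  }
  unif <- rep(1 / length(lab), length(lab))
  M[5, ] <- tapply(unif, lab, sum)[lev]
  M
}

# apply a rigid rotation + translation to a backbone_conformation
transform_conformation <- function(conf, R, t) {
  arr <- conf$coords
  for (i in seq_len(dim(arr)[1]))
    for (a in 1:3)
      arr[i, a, ] <- as.vector(R %*% arr[i, a, ]) + t
  conf$coords <- arr
  conf
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3)
}
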