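test_that("geometric ladders hit their endpoints with constant ratio", {
  lad <- make_ladder(300, 455.95, 64)
  expect_equal(lad[1], 300)
  expect_equal(lad[64], 455.95)
  r <- lad[-1] / lad[-64]
  expect_lt(max(r) - min(r), 1e-10)

  lad32 <- make_ladder(300, 452.32, 32)
  expect_equal(lad32[1], 300)
  expect_equal(lad32[32], 452.32)

  r2 <- 1.17
  expect_equal(as.numeric(make_ladder(300, 300 * r2, 2)), c(300, 300 * r2))
  expect_error(make_ladder(300, 400, 1), "at least 2")
  expect_error(make_ladder(400, 300, 8), "t_min < t_max")
})

test_that("exchange criterion matches its closed form and MC frequency", {
  expect_equal(exchange_attempt(10, 10, 300, 320), 1)
  expect_equal(exchange_attempt(3, 8, 310, 310), 1)
  # delta-beta * delta-E = -1 in natural units -> acceptance exp(-1)
  t_i <- 300; t_j <- 400
  dbeta <- 1 / (kB_kcal * t_i) - 1 / (kB_kcal * t_j)
  e_i <- 5; e_j <- e_i + 1 / dbeta   # (e_i - e_j) * dbeta = -1
  expect_equal(exchange_attempt(e_i, e_j, t_i, t_j), exp(-1),
               tolerance = 1e-12)
  set.seed(1)
  acc <- mean(replicate(1e5, exchange_attempt(e_i, e_j, t_i, t_j,
                                              draw = TRUE)))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 1e5)
  expect_lt(abs(acc - exp(-1)), 3 * se)
})

test_that("potential energies match a direct R evaluation of the formula", {
  pot <- torsion_potential(lubricin_model_peptide())
  set.seed(3)
  phi <- stats::runif(18, -180, 180); psi <- stats::runif(18, -180, 180)
  direct <- sapply(1:18, function(i) {
    s <- sum(pot$weights[i, ] *
               exp(pot$kappa * (cos((phi[i] - pot$centers[, 1]) * pi / 180) - 1) +
                   pot$kappa * (cos((psi[i] - pot$centers[, 2]) * pi / 180) - 1)))
    -pot$epsilon * log(s)
  })
  expect_equal(potential_energy(pot, phi, psi), direct, tolerance = 1e-12)
})

test_that("zero step leaves the state unchanged; infinite T accepts all", {
  pot <- torsion_potential(4)
  st <- list(phi = c(-75, -60, 100, 20), psi = c(145, -45, -170, 60))
  set.seed(5)
  out <- mc_sweep(st, pot, 300, step = 0, n_sweeps = 10)
  expect_equal(out$phi, st$phi)
  expect_equal(out$psi, st$psi)

  set.seed(5)
  hot <- mc_sweep(st, pot, 1e9, step = 45, n_sweeps = 1)
  expect_true(all(hot$phi != st$phi))   # every proposal accepted
  expect_true(all(hot$psi != st$psi))
})

test_that("single-replica REMD is bitwise identical to a Metropolis loop", {
  pot <- torsion_potential(3)
  cfg <- mc_config(sweeps = 200, step = 45, record_every = 200,
                   burn_in = 0, seed = 99)
  run <- run_remd(pot, 300, cfg)
  set.seed(99)
  manual <- mc_sweep(list(phi = rep(-75, 3), psi = rep(145, 3)),
                     pot, 300, step = 45, n_sweeps = 200)
  expect_identical(as.vector(run$series[[1]]$phi[1, ]), manual$phi)
  expect_identical(as.vector(run$series[[1]]$psi[1, ]), manual$psi)
})

test_that("identical seeds give identical replica runs", {
  pot <- torsion_potential(threonine_tetrapeptide())
  lad <- make_ladder(300, 452.32, 4)
  cfg <- mc_config(sweeps = 2000, seed = 17)
  a <- run_remd(pot, lad, cfg)
  b <- run_remd(pot, lad, cfg)
  expect_identical(a$series[[1]]$phi, b$series[[1]]$phi)
  expect_identical(a$energy, b$energy)
  expect_identical(a$exchange_rates, b$exchange_rates)
})

test_that("exchanges permute configurations without creating new ones", {
  # with step 0 the Metropolis moves never alter a configuration, so
  # every recorded frame must hold a permutation of the distinct
  # initial configurations across temperature slots
  pot <- torsion_potential(2)
  K <- 4
  init <- list(phi = matrix(seq(-150, 30, by = 60) + rep(0:1, each = K),
                            K, 2),
               psi = matrix(rep(145, 2 * K), K, 2))
  cfg <- mc_config(sweeps = 100, step = 0, exchange_every = 5,
                   record_every = 5, burn_in = 0, seed = 2)
  run <- run_remd(pot, make_ladder(300, 455.95, K), cfg, init = init)
  key0 <- sort(apply(init$phi, 1, paste, collapse = "/"))
  for (f in seq_len(nrow(run$energy))) {
    frame <- sapply(run$series, function(s) paste(s$phi[f, ], collapse = "/"))
    expect_identical(sort(frame), key0)
  }
  expect_true(all(run$exchange_rates >= 0 & run$exchange_rates <= 1))
})

test_that("Metropolis sampling recovers the grid Boltzmann distribution", {
  pot <- single_basin_potential()
  cfg <- mc_config(sweeps = 1e5, step = 60, record_every = 1,
                   burn_in = 0.1, seed = 3)
  s <- cold_series(run_remd(pot, 300, cfg))
  h <- ramachandran_histogram(s, bins = 72)
  P <- grid_boltzmann(pot, 300, bins = 72)
  expect_lt(0.5 * sum(abs(h$prob - P)), 0.05)
})

test_that("exchange acceptance drops as the ladder widens", {
  pot <- torsion_potential(lubricin_model_peptide(FALSE))
  cfg <- mc_config(sweeps = 5000, seed = 21)
  narrow <- run_remd(pot, make_ladder(300, 340, 4), cfg)
  wide <- run_remd(pot, make_ladder(300, 600, 4), cfg)
  expect_true(all(narrow$exchange_rates > 0 & narrow$exchange_rates < 1))
  expect_true(all(wide$exchange_rates > 0 & wide$exchange_rates < 1))
  expect_gt(mean(narrow$exchange_rates), mean(wide$exchange_rates))
})

test_that("PPII-dominant potential yields PPII-ranked 300 K populations", {
  pot <- torsion_potential(lubricin_model_peptide(FALSE))
  run <- run_remd(pot, make_ladder(300, 455.95, 8),
                  mc_config(sweeps = 2e4, seed = 4))
  pools <- colMeans(region_populations(cold_series(run))$fraction)
  expect_identical(names(which.max(pools)), "PPII")
  # oracle: quadrature of the Boltzmann weight over each region
  P <- grid_boltzmann(pot, 300, bins = 360)
  g <- seq(-179.5, 179.5, by = 1)
  lab <- classify_region(rep(g, times = 360), rep(g, each = 360))
  mass <- tapply(as.vector(P), lab, sum)
  expect_identical(names(which.max(mass)), "PPII")
})

test_that("glycosylated threonines lose alpha_R and gain PPII occupancy", {
  lad <- make_ladder(300, 455.95, 8)
  cfg <- mc_config(sweeps = 4e4, seed = 11)
  pn <- region_populations(cold_series(
    run_remd(torsion_potential(lubricin_model_peptide(FALSE)), lad, cfg)))
  pg <- region_populations(cold_series(
    run_remd(torsion_potential(lubricin_model_peptide(TRUE)), lad, cfg)))
  thr <- as.character(c(399, 400, 407, 408))
  expect_true(all(pg$fraction[thr, "alpha_R"] < pn$fraction[thr, "alpha_R"]))
  expect_true(all(pg$fraction[thr, "PPII"] > pn$fraction[thr, "PPII"]))
})
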