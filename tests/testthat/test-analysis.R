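test_that("ramachandran histograms bin and normalise correctly", {
  s <- dihedral_series(matrix(-75, 10, 2), matrix(145, 10, 2))
  h <- ramachandran_histogram(s, bins = 72)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_identical(sum(h$counts > 0), 1L)
  expect_equal(max(h$prob), 1)

  two <- dihedral_series(matrix(c(-75, 60), 10, 1),
                         matrix(c(145, 45), 10, 1))
  h2 <- ramachandran_histogram(two, bins = 36)
  expect_equal(sort(h2$prob[h2$prob > 0]), c(0.5, 0.5))

  expect_error(ramachandran_histogram(
    dihedral_series(matrix(NA_real_, 2, 1), matrix(NA_real_, 2, 1))),
    "no defined")
})

test_that("uniform angles fill the histogram uniformly", {
  set.seed(8)
  n <- 1e6
  s <- dihedral_series(matrix(stats::runif(n, -180, 180), ncol = 1),
                       matrix(stats::runif(n, -180, 180), ncol = 1))
  h <- ramachandran_histogram(s, bins = 72)
  p0 <- 1 / 72^2
  se <- sqrt(p0 * (1 - p0) / n)
  # every bin near the uniform value; 4.5 se covers the expected maximum
  # deviation across 5184 bins
  expect_lt(max(abs(h$prob - p0)), 4.5 * se)
})

test_that("Boltzmann inversion reproduces the hand-evaluated two-bin case", {
  fes <- free_energy_surface(c(0.8, 0.2), temperature = 300)
  expect_equal(fes$delta_g[1], 0)
  expect_equal(fes$delta_g[2], -kB_kcal * 300 * log(0.25), tolerance = 1e-12)
  expect_equal(fes$delta_g[2], 0.826, tolerance = 1e-3)
})

test_that("free-energy surfaces obey their invariants", {
  set.seed(9)
  s <- dihedral_series(matrix(stats::runif(4000, -180, 180), ncol = 2),
                       matrix(stats::runif(4000, -180, 180), ncol = 2))
  h <- ramachandran_histogram(s, bins = 24)
  fes <- free_energy_surface(h, 300)
  expect_equal(sum(fes$prob), 1, tolerance = 1e-12)
  expect_equal(min(fes$delta_g, na.rm = TRUE), 0)
  expect_true(all(fes$delta_g >= 0, na.rm = TRUE))
  expect_identical(fes$delta_g[fes$argmin], 0)
  # empty bins are masked as undefined, never zero
  expect_identical(is.na(fes$delta_g), fes$prob == 0)

  # uniform probability: zero free energy everywhere defined
  u <- free_energy_surface(rep(0.25, 4), 300)
  expect_equal(u$delta_g, rep(0, 4))

  # temperature scaling is exactly linear bin-wise
  f2 <- free_energy_surface(h, 450)
  expect_equal(f2$delta_g, fes$delta_g * 450 / 300, tolerance = 1e-10)

  expect_error(free_energy_surface(c(0.4, 0.2), 300), "sum to 1")
  expect_error(free_energy_surface(c(0.5, 0.5), -10), "positive")
})

test_that("classification matches the printed bounds and the lift rule", {
  expect_identical(as.character(classify_region(-75, 145)), "PPII")
  expect_identical(as.character(classify_region(-60, -45)), "alpha_R")
  expect_identical(as.character(classify_region(150, 0)), "coil")
  expect_identical(as.character(classify_region(-135, 135)), "beta")
  expect_identical(as.character(classify_region(60, 45)), "alpha_L")
  # psi lift: -150 tests as 210, inside (50, 240)
  expect_identical(as.character(classify_region(-120, -150)), "beta")
  expect_identical(as.character(classify_region(-60, -150)), "PPII")
  # strict inequalities: boundary values fall to coil
  expect_identical(as.character(classify_region(-90, 100)), "coil")
  expect_identical(as.character(classify_region(-75, 50)), "coil")
  expect_error(classify_region(NA, 0), "finite")
})

test_that("named regions are disjoint and classification total on a 1-degree grid", {
  g <- seq(-179.5, 179.5, by = 1)
  phi <- rep(g, times = length(g))
  psi <- rep(g, each = length(g))
  lab <- as.character(classify_region(phi, psi))
  expect_false(anyNA(lab))
  # brute-force oracle: independent scalar implementation of each bound
  idx <- seq(1, length(phi), by = 7)   # systematic subsample for speed
  oracle <- vapply(idx, function(i) oracle_region(phi[i], psi[i]), "")
  expect_identical(lab[idx], oracle)
})

test_that("region populations recover known compositions", {
  s <- dihedral_series(matrix(-75, 50, 3), matrix(145, 50, 3))
  p <- region_populations(s)
  expect_equal(unname(p$fraction[, "PPII"]), rep(1, 3))
  expect_equal(unname(rowSums(p$fraction)), rep(1, 3), tolerance = 1e-12)

  one <- region_populations(dihedral_series(matrix(-60, 1, 1),
                                            matrix(-45, 1, 1)))
  expect_equal(sort(unname(one$fraction[1, ]), decreasing = TRUE)[1], 1)
  expect_equal(unname(one$fraction[1, "alpha_R"]), 1)
})

test_that("population fractions are invariant to frame permutation", {
  spec <- generator_spec(n_frames = 500, n_residues = 2, seed = 31)
  s <- sample_ensemble(spec)$series
  p1 <- region_populations(s)$fraction
  set.seed(1)
  p2 <- region_populations(subset_frames(s, sample(500)))$fraction
  expect_equal(p1, p2)
})

test_that("bootstrap intervals bracket the estimate and are reproducible", {
  spec <- generator_spec(n_frames = 400, n_residues = 2, rho = 0.9,
                         seed = 13)
  s <- sample_ensemble(spec)$series
  ci1 <- population_ci(s, n_boot = 100, seed = 5)
  ci2 <- population_ci(s, n_boot = 100, seed = 5)
  expect_identical(ci1$lower, ci2$lower)
  expect_identical(ci1$upper, ci2$upper)
  expect_true(all(ci1$lower <= ci1$fraction + 1e-12))
  expect_true(all(ci1$upper >= ci1$fraction - 1e-12))

  const <- dihedral_series(matrix(-75, 50, 1), matrix(145, 50, 1))
  cc <- population_ci(const, n_boot = 50, seed = 1)
  expect_equal(unname(cc$lower[1, "PPII"]), 1)
  expect_equal(unname(cc$upper[1, "PPII"]), 1)

  tiny <- dihedral_series(matrix(-75, 3, 1), matrix(145, 3, 1))
  expect_error(population_ci(tiny, block_length = 2), "too few frames")
})

test_that("comparing a table with itself flags nothing", {
  spec <- generator_spec(n_frames = 300, n_residues = 3, seed = 23)
  s <- sample_ensemble(spec)$series
  p <- region_populations(s)
  cmp <- compare_populations(p, p, n_boot = 100, seed = 9)
  expect_false(any(cmp$significant))
  expect_equal(cmp$difference, rep(0, nrow(cmp)))
})

test_that("mismatched population tables are rejected", {
  a <- region_populations(sample_ensemble(
    generator_spec(n_frames = 100, n_residues = 2, seed = 1))$series)
  b <- region_populations(sample_ensemble(
    generator_spec(n_frames = 100, n_residues = 3, seed = 1))$series)
  expect_error(compare_populations(a, b), "mismatched")
})
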