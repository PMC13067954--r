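test_that("generator specs validate and normalise weights", {
  spec <- generator_spec(c(PPII = 2, alpha_R = 1, beta = 1, alpha_L = 0,
                           coil = 0), n_frames = 10, n_residues = 3)
  expect_equal(rowSums(spec$weights), rep(1, 3))
  expect_equal(unname(spec$weights[1, "PPII"]), 0.5)
  expect_error(generator_spec(c(PPII = -1, alpha_R = 1, beta = 1,
                                alpha_L = 0, coil = 1)), "nonnegative")
  expect_error(generator_spec(rho = 1), "rho < 1")
})

test_that("identical seeds reproduce the ensemble exactly", {
  spec <- generator_spec(n_frames = 200, n_residues = 4, seed = 77)
  a <- sample_ensemble(spec)
  b <- sample_ensemble(spec)
  expect_identical(a$series$phi, b$series$phi)
  expect_identical(a$labels, b$labels)
})

test_that("a pure tight PPII generator classifies as PPII every frame", {
  spec <- generator_spec(c(PPII = 1, alpha_R = 0, beta = 0, alpha_L = 0,
                           coil = 0), n_frames = 500, kappa = 300,
                         seed = 41)
  out <- sample_ensemble(spec)
  lab <- classify_region(out$series$phi, out$series$psi)
  expect_true(all(lab == "PPII"))
})

test_that("label chains are stationary with the requested stickiness", {
  # stationarity: transition matrix rho*I + (1-rho)*1 pi' has stationary
  # eigenvector pi, so empirical frequencies match the weights within
  # autocorrelation-adjusted binomial error
  w <- c(PPII = 0.5, alpha_R = 0.2, beta = 0.2, alpha_L = 0.05,
         coil = 0.05)
  rho <- 0.9
  n <- 5e4
  spec <- generator_spec(w, n_frames = n, n_residues = 1, rho = rho,
                         seed = 55)
  lab <- sample_ensemble(spec)$labels[, 1]
  inflate <- sqrt((1 + rho) / (1 - rho))
  for (k in 1:5) {
    p <- w[k] / sum(w)
    se <- sqrt(p * (1 - p) / n) * inflate
    expect_lt(abs(mean(lab == k) - p), 3 * se)
  }
})

test_that("rho = 0 gives uncorrelated labels, rho = 0.9 sticky ones", {
  lag1 <- function(x) stats::cor(x[-1], x[-length(x)])
  n <- 2e4
  iid <- sample_ensemble(generator_spec(n_frames = n, rho = 0,
                                        seed = 3))$labels[, 1]
  expect_lt(abs(lag1(iid)), 3 / sqrt(n))
  sticky <- sample_ensemble(generator_spec(n_frames = n, rho = 0.9,
                                           seed = 3))$labels[, 1]
  expect_gt(lag1(sticky), 0.8)
})

test_that("sampled region fractions match the quadrature push-forward", {
  w <- c(PPII = 0.7, alpha_R = 0, beta = 0.3, alpha_L = 0, coil = 0)
  n <- 2e4
  spec <- generator_spec(w, n_frames = n, rho = 0, kappa = 8, seed = 29)
  s <- sample_ensemble(spec)$series
  frac <- region_populations(s)$fraction[1, ]
  truth <- as.vector(t(spec$weights[1, ]) %*% generator_confusion(8))
  names(truth) <- colnames(generator_confusion(8))
  for (r in names(frac)) {
    se <- sqrt(truth[r] * (1 - truth[r]) / n) + 1e-4  # + quadrature slack
    expect_lt(abs(frac[r] - truth[r]), 3 * se + 2e-3)
  }
})

test_that("tight-concentration generators recover their weights directly", {
  w <- c(PPII = 0.7, alpha_R = 0, beta = 0.3, alpha_L = 0, coil = 0)
  n <- 1e5
  s <- sample_ensemble(generator_spec(w, n_frames = n, rho = 0,
                                      kappa = 128, seed = 37))$series
  frac <- region_populations(s)$fraction[1, ]
  expect_lt(abs(frac[["PPII"]] - 0.7), 3 * sqrt(0.7 * 0.3 / n) + 2e-3)
  expect_lt(abs(frac[["beta"]] - 0.3), 3 * sqrt(0.7 * 0.3 / n) + 2e-3)
})

test_that("paired ensembles differ only at the affected threonines", {
  base <- generator_spec(n_frames = 400,
                         peptide = lubricin_model_peptide(), seed = 61)
  pair <- paired_glyco_ensembles(base)
  # affected: the 4 glycosylated threonines plus cooperative Thr401
  expect_identical(pair$affected_residues,
                   c(399L, 400L, 401L, 407L, 408L))
  # identity effect: same generator law and seed -> identical series
  same <- paired_glyco_ensembles(base, alpha_factor = 1)
  expect_identical(same$nonglyco$series$phi, same$glyco$series$phi)
  expect_identical(same$affected_residues, integer())
})

test_that("the glyco effect empties alpha_R at affected threonines only", {
  base <- generator_spec(n_frames = 4000, rho = 0,
                         peptide = lubricin_model_peptide(), seed = 67)
  pair <- paired_glyco_ensembles(base, alpha_factor = 0.02)
  pg <- region_populations(pair$glyco$series)$fraction
  pn <- region_populations(pair$nonglyco$series)$fraction
  thr <- as.character(pair$affected_residues)
  other <- setdiff(rownames(pg), thr)
  expect_true(all(pg[thr, "alpha_R"] < 0.03))     # almost zero
  expect_true(all(pg[thr, "alpha_R"] < pn[thr, "alpha_R"]))
  expect_true(all(pg[thr, "PPII"] > pn[thr, "PPII"]))
  # unaffected residues: same law, differences are pure noise
  expect_lt(max(abs(pg[other, ] - pn[other, ])), 0.05)
})
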