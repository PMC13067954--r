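#' Ramachandran probability histogram
#'
#' Bins all defined (phi, psi) observations of a dihedral ensemble on a
#' regular grid covering the full torus (-180, 180] x (-180, 180] and
#' normalises to a probability distribution. By default observations are
#' pooled over all residues and frames (the whole-peptide surface); a
#' residue subset can be selected.
#'
#' @param series A [dihedral_series()].
#' @param bins Number of bins per axis (default 72, i.e. 5-degree bins).
#' @param residues Optional integer vector of residue numbers to pool.
#' @return Object of class `rama_hist`: list with `prob` (bins x bins
#'   matrix, phi rows, psi columns, summing to 1), `counts`, `phi_edges`,
#'   `psi_edges` and `n`.
#' @export
ramachandran_histogram <- function(series, bins = 72, residues = NULL) {
  stopifnot(inherits(series, "dihedral_series"), bins >= 1)
  phi <- series$phi; psi <- series$psi
  if (!is.null(residues)) {
    j <- match(residues, series$residue_numbers)
    if (anyNA(j)) stop("unknown residue numbers")
    phi <- phi[, j, drop = FALSE]; psi <- psi[, j, drop = FALSE]
  }
  ok <- !is.na(phi) & !is.na(psi)
  phi <- phi[ok]; psi <- psi[ok]
  if (!length(phi)) stop("no defined (phi, psi) observations")
  w <- 360 / bins
  ip <- pmin(bins, pmax(1L, ceiling((phi + 180) / w)))
  is_ <- pmin(bins, pmax(1L, ceiling((psi + 180) / w)))
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(ip, levels = 1:bins), factor(is_, levels = 1:bins))
  counts[] <- as.integer(tab)
  edges <- seq(-180, 180, by = w)
  structure(list(prob = counts / sum(counts), counts = counts,
                 phi_edges = edges, psi_edges = edges, n = length(phi)),
            class = "rama_hist")
}

#' @export
print.rama_hist <- function(x, ...) {
  cat(sprintf("Ramachandran histogram: %dx%d bins, %d observations, %d occupied\n",
              nrow(x$prob), ncol(x$prob), x$n, sum(x$counts > 0)))
  invisible(x)
}

#' Free-energy surface by Boltzmann inversion
#'
#' Converts a normalised probability distribution over (phi, psi) bins
#' into a free-energy surface relative to the global minimum,
#' \deqn{\Delta G(\phi,\psi) = -k_B T \ln\left(P(\phi,\psi)/P_{max}\right),}
#' where `P_max` is the probability of the most occupied bin. The surface
#' is zero at the global minimum and nonnegative elsewhere; bins with no
#' observations have undefined (not infinite) free energy and are
#' returned as `NA`, which keeps surfaces plottable and comparable.
#'
#' @param p A `rama_hist`, or a numeric array of bin probabilities
#'   summing to 1 (tolerance `tol`).
#' @param temperature Temperature in kelvin.
#' @param tol Normalisation tolerance.
#' @return Object of class `free_energy_surface`: list with `delta_g`
#'   (kcal/mol, `NA` for empty bins), `prob`, `temperature`, `kB`,
#'   `p_max`, `argmin` (index of the minimum bin) and, when built from a
#'   `rama_hist`, the bin edges.
#' @examples
#' fes <- free_energy_surface(c(0.8, 0.2), temperature = 300)
#' fes$delta_g   # 0 and about 0.826 kcal/mol
#' @export
free_energy_surface <- function(p, temperature, tol = 1e-8) {
  if (temperature <= 0) stop("temperature must be positive")
  hist <- NULL
  if (inherits(p, "rama_hist")) { hist <- p; p <- p$prob }
  if (any(p < 0, na.rm = TRUE)) stop("probabilities must be nonnegative")
  if (abs(sum(p, na.rm = TRUE) - 1) > tol)
    stop("probabilities must sum to 1; normalise the histogram first")
  p_max <- max(p, na.rm = TRUE)
  dg <- -kB_kcal * temperature * log(p / p_max)
  dg[!is.na(p) & p == 0] <- NA_real_
  dims <- if (is.null(dim(p))) length(p) else dim(p)
  structure(list(delta_g = dg, prob = p, temperature = temperature,
                 kB = kB_kcal, p_max = p_max,
                 argmin = arrayInd(which.max(p), dims),
                 phi_edges = hist$phi_edges, psi_edges = hist$psi_edges),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("Free-energy surface at %.1f K: range 0-%.2f kcal/mol over defined bins\n",
              x$temperature, max(x$delta_g, na.rm = TRUE)))
  if (!is.null(x$phi_edges)) {
    am <- x$argmin
    cat(sprintf("  global minimum bin centred at (%.0f, %.0f) deg\n",
                (x$phi_edges[am[1]] + x$phi_edges[am[1] + 1]) / 2,
                (x$psi_edges[am[2]] + x$psi_edges[am[2] + 1]) / 2))
  }
  invisible(x)
}

#' Plot a free-energy surface as a Ramachandran heatmap
#'
#' @param x A `free_energy_surface` built from a [ramachandran_histogram()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.free_energy_surface <- function(x, ...) {
  if (is.null(x$phi_edges)) stop("surface has no bin-edge information")
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  graphics::image(mids(x$phi_edges), mids(x$psi_edges), x$delta_g,
                  xlab = expression(phi ~ "(deg)"),
                  ylab = expression(psi ~ "(deg)"),
                  col = grDevices::hcl.colors(64, "viridis", rev = TRUE), ...)
  graphics::box()
  invisible(x)
}

#' Secondary-structure regions of the Ramachandran plot
#'
#' The literature region bounds used for population analysis:
#' alpha_R: -160 < phi < -20 and -120 < psi < 50;
#' beta: -180 < phi < -90 and 50 < psi < 240;
#' PPII: -90 < phi < 20 and 50 < psi < 240;
#' alpha_L: 30 < phi < 100 and 0 < psi < 80; coil is everything else.
#' All inequalities are strict, so exact boundary values classify as
#' coil. For regions whose upper psi bound exceeds 180 (beta and PPII
#' reach 240), a psi value below `upper - 360` is lifted by 360 degrees
#' before testing, so psi = -150 tests as 210.
#'
#' @param bounds Data frame with columns `name`, `phi_lo`, `phi_hi`,
#'   `psi_lo`, `psi_hi` (degrees) overriding the defaults.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(bounds = NULL) {
  if (is.null(bounds)) {
    bounds <- data.frame(
      name = c("alpha_R", "beta", "PPII", "alpha_L"),
      phi_lo = c(-160, -180, -90, 30),
      phi_hi = c(-20, -90, 20, 100),
      psi_lo = c(-120, 50, 50, 0),
      psi_hi = c(50, 240, 240, 80))
  }
  stopifnot(all(c("name", "phi_lo", "phi_hi", "psi_lo", "psi_hi") %in%
                  names(bounds)))
  structure(list(bounds = bounds,
                 levels = c(bounds$name, "coil")),
            class = "region_spec")
}

#' Classify (phi, psi) pairs into secondary-structure regions
#'
#' Vectorised total classification under a [region_spec()]: every finite
#' angle pair receives exactly one label, with coil as the complement of
#' the named regions.
#'
#' @param phi,psi Numeric vectors of angles in degrees on (-180, 180].
#' @param regions A [region_spec()].
#' @return Factor of region labels with levels `c(region names, "coil")`.
#' @examples
#' classify_region(-75, 145)    # PPII
#' classify_region(-60, -45)    # alpha_R
#' @export
classify_region <- function(phi, psi, regions = region_spec()) {
  if (any(!is.finite(phi)) || any(!is.finite(psi)))
    stop("classify_region requires finite angles; drop NA terminal angles first")
  stopifnot(length(phi) == length(psi))
  b <- regions$bounds
  lab <- rep.int("coil", length(phi))
  for (r in seq_len(nrow(b))) {
    ps <- psi
    if (b$psi_hi[r] > 180) {
      lift <- ps < b$psi_hi[r] - 360
      ps[lift] <- ps[lift] + 360
    }
    hit <- phi > b$phi_lo[r] & phi < b$phi_hi[r] &
      ps > b$psi_lo[r] & ps < b$psi_hi[r]
    lab[hit] <- b$name[r]
  }
  factor(lab, levels = regions$levels)
}

#' Per-residue secondary-structure region populations
#'
#' Fraction of frames each residue spends in each Ramachandran region.
#' Fractions sum to one per residue; residues whose angles are entirely
#' undefined (chain termini in coordinate-derived series) are dropped.
#'
#' @param series A [dihedral_series()].
#' @param regions A [region_spec()].
#' @return Object of class `region_populations`: list with `fraction`
#'   (residues x regions matrix), `n_frames`, `residue_numbers`,
#'   `regions`, and the per-frame label matrix `labels` (integer codes)
#'   used for bootstrap resampling.
#' @export
region_populations <- function(series, regions = region_spec()) {
  stopifnot(inherits(series, "dihedral_series"))
  ok_res <- colSums(!is.na(series$phi) & !is.na(series$psi)) > 0
  phi <- series$phi[, ok_res, drop = FALSE]
  psi <- series$psi[, ok_res, drop = FALSE]
  if (!ncol(phi)) stop("no residues with defined angles")
  nf <- nrow(phi); nr <- ncol(phi)
  lev <- regions$levels
  lab <- matrix(NA_integer_, nf, nr)
  defined <- !is.na(phi) & !is.na(psi)
  lab[defined] <- as.integer(classify_region(phi[defined], psi[defined],
                                             regions))
  frac <- t(apply(lab, 2, function(col) {
    tabulate(col[!is.na(col)], nbins = length(lev)) / sum(!is.na(col))
  }))
  dimnames(frac) <- list(series$residue_numbers[ok_res], lev)
  structure(list(fraction = frac, n_frames = nf,
                 residue_numbers = series$residue_numbers[ok_res],
                 regions = regions, labels = lab),
            class = "region_populations")
}

#' @export
print.region_populations <- function(x, digits = 3, ...) {
  cat(sprintf("Region populations: %d residues x %d regions (%d frames)\n",
              nrow(x$fraction), ncol(x$fraction), x$n_frames))
  print(round(x$fraction, digits))
  if (!is.null(x$lower)) cat(sprintf("with %.0f%% bootstrap confidence intervals\n",
                                     100 * x$level))
  invisible(x)
}

#' @export
as.data.frame.region_populations <- function(x, ...) {
  d <- data.frame(residue = rep(x$residue_numbers,
                                times = ncol(x$fraction)),
                  region = rep(colnames(x$fraction),
                               each = nrow(x$fraction)),
                  fraction = as.vector(x$fraction))
  if (!is.null(x$lower)) {
    d$lower <- as.vector(x$lower)
    d$upper <- as.vector(x$upper)
  }
  d
}

# moving-block bootstrap frame indices: contiguous blocks of length L
# preserve short-range autocorrelation of the chain
block_boot_index <- function(n, block_length) {
  nb <- ceiling(n / block_length)
  starts <- sample.int(n - block_length + 1, nb, replace = TRUE)
  idx <- rep(starts, each = block_length) +
    rep.int(seq_len(block_length) - 1L, nb)
  idx[seq_len(n)]
}

#' Region populations with moving-block bootstrap confidence intervals
#'
#' Percentile bootstrap intervals for each residue x region occupancy
#' fraction. Frames are resampled in contiguous blocks so that the
#' temporal autocorrelation of the underlying trajectory is respected;
#' the default block length is `ceiling(n^(1/3))` frames.
#'
#' @param series A [dihedral_series()].
#' @param regions A [region_spec()].
#' @param level Confidence level (default 0.95).
#' @param block_length Block length in frames.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed for reproducible intervals.
#' @return A `region_populations` object with additional `lower`,
#'   `upper`, `level`, `block_length` and `n_boot` fields.
#' @export
population_ci <- function(series, regions = region_spec(), level = 0.95,
                          block_length = NULL, n_boot = 500, seed = NULL) {
  pop <- region_populations(series, regions)
  n <- pop$n_frames
  if (is.null(block_length)) block_length <- ceiling(n^(1 / 3))
  if (n < 2 * block_length)
    stop("too few frames for block bootstrap (need at least 2 blocks)")
  if (!is.null(seed)) set.seed(seed)
  lev <- regions$levels
  nr <- nrow(pop$fraction)
  boots <- array(NA_real_, c(n_boot, nr, length(lev)))
  for (b in seq_len(n_boot)) {
    idx <- block_boot_index(n, block_length)
    lab <- pop$labels[idx, , drop = FALSE]
    boots[b, , ] <- t(apply(lab, 2, function(col) {
      tabulate(col[!is.na(col)], nbins = length(lev)) / sum(!is.na(col))
    }))
  }
  a <- (1 - level) / 2
  qs <- apply(boots, c(2, 3), stats::quantile, probs = c(a, 1 - a),
              names = FALSE)
  pop$lower <- pmin(matrix(qs[1, , ], nrow = nr), pop$fraction)
  pop$upper <- pmax(matrix(qs[2, , ], nrow = nr), pop$fraction)
  dimnames(pop$lower) <- dimnames(pop$upper) <- dimnames(pop$fraction)
  pop$level <- level
  pop$block_length <- block_length
  pop$n_boot <- n_boot
  pop
}

#' Compare per-residue region populations between two ensembles
#'
#' Flags residue x region cells whose occupancy differs both practically
#' and statistically between two ensembles (e.g. glycosylated versus
#' nonglycosylated). Statistical significance comes from a null-resampled
#' moving-block bootstrap test of the difference of fractions: frames of
#' both ensembles are pooled (imposing the null of a common law),
#' bootstrap pairs of pseudo-ensembles are drawn from the pool, and the
#' two-sided p-value is the fraction of null differences at least as
#' large as the observed one. Resampling under the null keeps the test
#' calibrated even for short series, where interval inversion is
#' anticonservative for proportions. Practical significance requires the
#' point difference to exceed `practical` in absolute value; a cell is
#' flagged only when both hold, matching the notion of a practically and
#' statistically significant population shift. A moving-block bootstrap
#' percentile interval for the difference is reported alongside as the
#' effect-size summary.
#'
#' @param table_a,table_b `region_populations` objects on matching
#'   residues and regions (as returned by [region_populations()] or
#'   [population_ci()]).
#' @param alpha Significance level of the null-bootstrap test.
#' @param practical Minimum absolute difference in occupancy regarded as
#'   practically relevant.
#' @param block_length Block length; defaults per ensemble to
#'   `ceiling(n^(1/3))`.
#' @param n_boot Bootstrap replicates (used for both the null test and
#'   the effect-size interval).
#' @param seed Optional seed.
#' @return Data frame with columns `residue`, `region`, `fraction_a`,
#'   `fraction_b`, `difference` (b - a), `ci_lower`, `ci_upper` (percentile
#'   interval of the difference at level `1 - alpha`), `p_value` and
#'   `significant`.
#' @export
compare_populations <- function(table_a, table_b, alpha = 0.05,
                                practical = 0.05, block_length = NULL,
                                n_boot = 500, seed = NULL) {
  stopifnot(inherits(table_a, "region_populations"),
            inherits(table_b, "region_populations"))
  if (!identical(table_a$residue_numbers, table_b$residue_numbers) ||
      !identical(colnames(table_a$fraction), colnames(table_b$fraction)))
    stop("population tables have mismatched residues or regions")
  if (!is.null(seed)) set.seed(seed)
  lev <- colnames(table_a$fraction)
  nr <- nrow(table_a$fraction)
  na <- table_a$n_frames; nb <- table_b$n_frames
  frac_of <- function(lab) t(apply(lab, 2, function(col) {
    tabulate(col[!is.na(col)], nbins = length(lev)) / sum(!is.na(col))
  }))
  bl_a <- if (is.null(block_length)) ceiling(na^(1 / 3)) else block_length
  bl_b <- if (is.null(block_length)) ceiling(nb^(1 / 3)) else block_length
  point <- table_b$fraction - table_a$fraction

  # null distribution: both pseudo-ensembles resampled from the pooled
  # frames, imposing a common law
  pooled <- rbind(table_a$labels, table_b$labels)
  bl_p <- if (is.null(block_length)) ceiling((na + nb)^(1 / 3)) else block_length
  exceed <- matrix(0, nr, length(lev))
  diffs <- array(NA_real_, c(n_boot, nr, length(lev)))
  for (b in seq_len(n_boot)) {
    pa <- pooled[block_boot_index(na + nb, bl_p)[seq_len(na)], ,
                 drop = FALSE]
    pb <- pooled[block_boot_index(na + nb, bl_p)[seq_len(nb)], ,
                 drop = FALSE]
    null_diff <- frac_of(pb) - frac_of(pa)
    exceed <- exceed + (abs(null_diff) >= abs(point) - 1e-12)
    # effect-size interval: resample each ensemble from itself
    ia <- block_boot_index(na, bl_a)
    ib <- block_boot_index(nb, bl_b)
    diffs[b, , ] <- frac_of(table_b$labels[ib, , drop = FALSE]) -
      frac_of(table_a$labels[ia, , drop = FALSE])
  }
  p_val <- (exceed + 1) / (n_boot + 1)
  qs <- apply(diffs, c(2, 3), stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  sig <- p_val < alpha & abs(point) >= practical
  data.frame(residue = rep(table_a$residue_numbers, times = length(lev)),
             region = rep(lev, each = nr),
             fraction_a = as.vector(table_a$fraction),
             fraction_b = as.vector(table_b$fraction),
             difference = as.vector(point),
             ci_lower = as.vector(matrix(qs[1, , ], nrow = nr)),
             ci_upper = as.vector(matrix(qs[2, , ], nrow = nr)),
             p_value = as.vector(p_val),
             significant = as.vector(sig))
}
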