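test_that("angle wrapping maps onto (-180, 180]", {
  expect_equal(wrap_angle(c(200, -190, 180, -180, 540, 360)),
               c(-160, 170, 180, 180, 180, 0))
  expect_true(is.na(wrap_angle(NA)))
})

test_that("built backbones reproduce their input dihedrals exactly", {
  conf <- build_backbone(12, -75, 145)
  d <- backbone_dihedrals(conf)
  expect_equal(d$phi[-1], rep(-75, 11), tolerance = 1e-9)
  expect_equal(d$psi[-12], rep(145, 11), tolerance = 1e-9)
  expect_lt(max(abs(wrap_angle(d$omega[-12] - 180))), 1e-9)
  expect_true(is.na(conf$phi[1]) && is.na(conf$psi[12]))

  conf2 <- build_backbone(8, -57, -47)
  d2 <- backbone_dihedrals(conf2)
  expect_equal(d2$phi[-1], rep(-57, 7), tolerance = 1e-9)
  expect_equal(d2$psi[-8], rep(-47, 7), tolerance = 1e-9)
})

test_that("dihedral round trip holds for 1000 random chains", {
  set.seed(42)
  worst <- 0
  for (k in 1:1000) {
    n <- sample(3:7, 1)
    ph <- stats::runif(n, -180, 180)
    ps <- stats::runif(n, -180, 180)
    d <- backbone_dihedrals(build_backbone(n, ph, ps))
    worst <- max(worst,
                 abs(d$phi[-1] - wrap_angle(ph[-1])),
                 abs(d$psi[-n] - wrap_angle(ps[-n])))
  }
  expect_lt(worst, 1e-6)
})

test_that("built coordinates respect the covalent geometry", {
  geo <- backbone_geometry()
  conf <- build_backbone(6, c(NA, -60, 80, -120, 45, 170),
                         c(100, -30, 160, -80, 20, NA), geometry = geo)
  xyz <- conf$coords
  len <- function(a, b) sqrt(sum((a - b)^2))
  for (i in 1:6) {
    expect_equal(len(xyz[i, "N", ], xyz[i, "CA", ]),
                 unname(geo$lengths["b_n_ca"]), tolerance = 1e-9)
    expect_equal(len(xyz[i, "CA", ], xyz[i, "C", ]),
                 unname(geo$lengths["b_ca_c"]), tolerance = 1e-9)
    if (i < 6)
      expect_equal(len(xyz[i, "C", ], xyz[i + 1, "N", ]),
                   unname(geo$lengths["b_c_n"]), tolerance = 1e-9)
  }
})

test_that("degenerate chains and invalid geometry are rejected", {
  expect_error(build_backbone(1, -75, 145), "at least 2")
  expect_error(build_backbone(4, c(1, NA, 3, 4), rep(0, 4)), "finite")
  expect_error(backbone_geometry(b_n_ca = -1), "positive")
  expect_error(backbone_geometry(ang_n_ca_c = 185), "0, 180")
})

test_that("PPII and alpha geometries give their textbook helix parameters", {
  hp <- helix_parameters(build_backbone(12, -75, 145))
  expect_equal(hp$residues_per_turn, 3, tolerance = 0.05)
  expect_identical(hp$handedness, "left")

  ha <- helix_parameters(build_backbone(12, -57, -47))
  expect_equal(ha$residues_per_turn, 3.6, tolerance = 0.03)
  expect_identical(ha$handedness, "right")
  expect_equal(ha$rise_per_residue, 1.5, tolerance = 0.1)
})

test_that("helix twist agrees with independent frame-composition oracle", {
  # oracle: orthonormal frame from each residue's N/CA/C triad; the
  # relative rotation between consecutive frames gives the twist
  frame_of <- function(xyz, i) {
    e1 <- xyz[i, "CA", ] - xyz[i, "N", ]
    e1 <- e1 / sqrt(sum(e1^2))
    v <- xyz[i, "C", ] - xyz[i, "CA", ]
    e2 <- v - sum(v * e1) * e1
    e2 <- e2 / sqrt(sum(e2^2))
    cbind(e1, e2, c(e1[2] * e2[3] - e1[3] * e2[2],
                    e1[3] * e2[1] - e1[1] * e2[3],
                    e1[1] * e2[2] - e1[2] * e2[1]))
  }
  for (angles in list(c(-75, 145), c(-57, -47), c(-135, 135))) {
    conf <- build_backbone(10, angles[1], angles[2])
    Rrel <- frame_of(conf$coords, 5) %*% t(frame_of(conf$coords, 4))
    twist_oracle <- acos((sum(diag(Rrel)) - 1) / 2) * 180 / pi
    hp <- helix_parameters(conf)
    expect_equal(abs(hp$twist_per_residue), twist_oracle, tolerance = 1e-6)
  }
})

test_that("helix parameters are invariant to rigid motion", {
  conf <- build_backbone(10, -75, 145)
  hp <- helix_parameters(conf)
  set.seed(7)
  for (k in 1:5) {
    moved <- transform_conformation(conf, random_rotation(),
                                    stats::rnorm(3, sd = 10))
    hm <- helix_parameters(moved)
    expect_equal(hm$residues_per_turn, hp$residues_per_turn,
                 tolerance = 1e-6)
    expect_equal(hm$rise_per_residue, hp$rise_per_residue,
                 tolerance = 1e-6)
    expect_identical(hm$handedness, hp$handedness)
  }
})

test_that("helix fitting rejects short or non-uniform chains", {
  expect_error(helix_parameters(build_backbone(3, -75, 145)), "at least 6")
  mixed <- build_backbone(8, c(rep(-75, 4), rep(-57, 4)),
                          c(rep(145, 4), rep(-47, 4)))
  expect_error(helix_parameters(mixed), "not uniform")
})

test_that("extended PPII chain spans close to residues-1 times the rise", {
  conf <- build_backbone("PKEPAPTTTKEPAPTTPK", -75, 145)
  hp <- helix_parameters(conf)
  ext <- sqrt(sum((conf$coords[18, "CA", ] - conf$coords[1, "CA", ])^2))
  expect_equal(ext, 17 * hp$rise_per_residue, tolerance = 0.01)
})
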