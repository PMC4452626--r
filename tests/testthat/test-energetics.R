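# pairwise nonbonded energies, switching, LIE, pose combination, Kd ratios

atom_par <- function(q = 0, eps = 0, rmin_half = 0) {
  list(charge = q, lj_epsilon = eps, lj_rmin_half = rmin_half)
}

test_that("pair_energy reproduces closed-form LJ/Coulomb values", {
  p <- nonbonded_params()
  # beyond the cut-off: identically zero
  e <- pair_energy(atom_par(1, 0.2, 0.2), atom_par(1, 0.2, 0.2), 1.3, p)
  expect_identical(unname(e), c(0, 0))
  e <- pair_energy(atom_par(1, 0.2, 0.2), atom_par(1, 0.2, 0.2), 1.2, p)
  expect_identical(unname(e), c(0, 0))
  # LJ crosses zero at sigma = rmin * 2^(-1/6)
  rmin <- 0.2 + 0.18
  sigma <- rmin * 2^(-1 / 6)
  e <- pair_energy(atom_par(0, 0.3, 0.2), atom_par(0, 0.12, 0.18), sigma, p)
  expect_equal(unname(e["v_vdw"]), 0, tolerance = 1e-12)
  expect_equal(unname(e["v_el"]), 0)
  # LJ minimum at rmin equals -eps_ij
  e <- pair_energy(atom_par(0, 0.3, 0.2), atom_par(0, 0.12, 0.18), rmin, p)
  expect_equal(unname(e["v_vdw"]), -sqrt(0.3 * 0.12), tolerance = 1e-12)
  # Coulomb: two +1e charges at 0.5 nm inside the unswitched region
  e <- pair_energy(atom_par(1), atom_par(1), 0.5, p)
  expect_equal(unname(e["v_el"]), 33.2063711 / 0.5, tolerance = 1e-9)
  expect_equal(unname(e["v_el"]), 66.4127422, tolerance = 1e-6)
  # relative dielectric scales the Coulomb term down
  p80 <- nonbonded_params(relative_dielectric = 80)
  e80 <- pair_energy(atom_par(1), atom_par(1), 0.5, p80)
  expect_equal(unname(e80["v_el"]) * 80, unname(e["v_el"]), tolerance = 1e-12)
  expect_error(pair_energy(atom_par(1), atom_par(1), 0), "> 0")
})

test_that("the switching function is continuous at both knots and zero beyond", {
  p <- nonbonded_params()
  ai <- atom_par(0.7, 0.25, 0.21)
  aj <- atom_par(-0.4, 0.11, 0.19)
  for (knot in c(p$switch_on, p$cutoff)) {
    e0 <- pair_energy(ai, aj, knot, p)
    em <- pair_energy(ai, aj, knot - 1e-6, p)
    ep <- pair_energy(ai, aj, knot + 1e-6, p)
    expect_lt(max(abs(e0 - em)), 1e-4)
    expect_lt(max(abs(e0 - ep)), 1e-4)
  }
  expect_equal(switching_factor(0.9, p), 1)
  expect_equal(switching_factor(1.25, p), 0)
  # monotone decrease inside the switching window
  r <- seq(1.0, 1.2, by = 0.01)
  expect_true(all(diff(switching_factor(r, p)) <= 0))
})

test_that("ligand_environment_energy equals the brute-force double sum", {
  # one-pair system
  sys <- random_energy_system(1, n = 2)
  e1 <- ligand_environment_energy(sys$coords, sys$topology, 1L)
  a <- sys$topology$atoms
  r <- sqrt(sum((sys$coords[1, ] - sys$coords[2, ])^2))
  e_ref <- pair_energy(as.list(a[1, ]), as.list(a[2, ]), r)
  expect_equal(e1, e_ref, tolerance = 1e-12)
  # random 50-atom system vs the independent oracle
  sys <- random_energy_system(2, n = 50)
  e <- ligand_environment_energy(sys$coords, sys$topology, sys$ligand)
  o <- oracle_lig_env_energy(sys$coords, sys$topology, sys$ligand)
  expect_equal(unname(e), unname(o), tolerance = 1e-9)
  # all-zero parameters give zero energy
  sys$topology$atoms$charge[] <- 0
  sys$topology$atoms$lj_epsilon[] <- 0
  e <- ligand_environment_energy(sys$coords, sys$topology, sys$ligand)
  expect_equal(unname(e), c(0, 0))
  expect_error(ligand_environment_energy(sys$coords, sys$topology,
                                         seq_len(nrow(sys$topology$atoms))),
               "empty environment")
  expect_error(ligand_environment_energy(sys$coords, sys$topology, integer(0)),
               "empty ligand")
})

test_that("lie_free_energy implements the two-state formula with quadrature errors", {
  mk <- function(mv, me) energy_series(rep(mv, 10), rep(me, 10))
  r <- lie_free_energy(mk(-40, -20), mk(-30, -15))
  expect_equal(r$dg_bind, 0.18 * (-10) + 0.09 * (-5))
  expect_equal(r$dg_bind, -2.25)
  expect_equal(r$error, 0)
  # Kd consistency: negative dG => Kd < 1
  expect_lt(r$kd, 1)
  expect_equal(log(r$kd) * 1.9872e-3 * 298, r$dg_bind, tolerance = 1e-9)
  # identical states give zero
  r0 <- lie_free_energy(mk(-40, -20), mk(-40, -20))
  expect_equal(r0$dg_bind, 0)
  # linearity in both deltas
  set.seed(4)
  for (k in 1:20) {
    dv <- rnorm(1, sd = 10); de <- rnorm(1, sd = 10); cc <- runif(1, 0.1, 3)
    r1 <- lie_free_energy(mk(-30 + dv, -10 + de), mk(-30, -10))$dg_bind
    r2 <- lie_free_energy(mk(-30 + cc * dv, -10 + cc * de), mk(-30, -10))$dg_bind
    expect_equal(r2, cc * r1, tolerance = 1e-9)
    expect_equal(r1, 0.18 * dv + 0.09 * de, tolerance = 1e-9)
  }
})

test_that("combine_poses is a bounded, permutation-invariant Boltzmann average", {
  lp <- lie_parameters()
  rt <- 1.9872e-3 * 298
  expect_equal(combine_poses(c(A = -5)), -5)
  expect_equal(combine_poses(c(A = -5, B = -5)), -5, tolerance = 1e-12)
  # direct evaluation for {-8.0, -6.4}; with the equal-prior 1/N
  # normalization the combined value lies strictly inside
  # (min dG, min dG + RT ln N) for unequal poses
  dgs <- c(A = -8.0, B = -6.4)
  ref <- -rt * log(mean(exp(-dgs / rt)))
  got <- combine_poses(dgs)
  expect_equal(got, ref, tolerance = 1e-9)
  expect_gt(got, -8.0)
  expect_lt(got, -8.0 + rt * log(2))
  # permutation invariance
  expect_equal(combine_poses(rev(dgs)), got, tolerance = 1e-12)
  expect_error(combine_poses(numeric(0)), "no poses")
})

test_that("dissociation_ratio inverts free-energy gaps to fold differences", {
  rt <- 1.9872e-3 * 298
  expect_equal(dissociation_ratio(-5, -5), 1)
  expect_equal(dissociation_ratio(-5 - rt * log(20), -5), 20, tolerance = 1e-9)
  expect_equal(dissociation_ratio(-5 - rt * log(3), -5), 3, tolerance = 1e-9)
  # round trip with pose_preference
  set.seed(6)
  for (k in 1:20) {
    a <- rnorm(1, -7); b <- rnorm(1, -6)
    ddg <- pose_preference(a, b)
    expect_equal(rt * log(dissociation_ratio(a, b)), ddg, tolerance = 1e-9)
  }
})

test_that("pose_preference has the stated sign convention", {
  expect_equal(pose_preference(-7, -7), 0)
  expect_equal(pose_preference(-9.0, -7.4), 1.6)
  expect_equal(pose_preference(-7.4, -9.0), -1.6)
})
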