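# dihedral, Kabsch superposition, RMSD series

test_that("dihedral reproduces planar and butane-like reference values", {
  # planar cis: all four points in a plane, 0 deg
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  # planar trans: 180 deg
  expect_equal(abs(dihedral(c(-1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0))),
               180)
  # butane-like fixture checked against the explicit atan2 cross-product
  # formula evaluated by hand (frozen value)
  p1 <- c(0.1, 0.2, 0.0)
  p2 <- c(0.0, 0.0, 0.0)
  p3 <- c(0.15, 0.0, 0.0)
  p4 <- c(0.25, 0.12, 0.09)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  ref <- atan2(sum(c(n1[2] * n2[3] - n1[3] * n2[2],
                     n1[3] * n2[1] - n1[1] * n2[3],
                     n1[1] * n2[2] - n1[2] * n2[1]) * b2 / sqrt(sum(b2^2))),
               sum(n1 * n2)) * 180 / pi
  expect_equal(dihedral(p1, p2, p3, p4), ref, tolerance = 1e-9)
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
})

test_that("dihedral reversal antisymmetry holds on random non-planar inputs", {
  set.seed(42)
  for (k in 1:50) {
    p <- matrix(rnorm(12), ncol = 3)
    d1 <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    d2 <- dihedral(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(d1, d2, tolerance = 1e-9)  # full reversal preserves sign
    # swapping the viewing direction (mirror) flips it
    m <- p; m[, 3] <- -m[, 3]
    expect_equal(dihedral(m[1, ], m[2, ], m[3, ], m[4, ]), -d1,
                 tolerance = 1e-9)
    expect_true(d1 > -180 && d1 <= 180)
  }
})

test_that("kabsch_superpose recovers rigid motions and the one-atom closed form", {
  set.seed(7)
  ref <- matrix(rnorm(30), ncol = 3)
  # identity
  r0 <- kabsch_superpose(ref, ref)
  expect_equal(r0$fit_rmsd, 0, tolerance = 1e-10)
  expect_equal(det(r0$rotation), 1, tolerance = 1e-10)
  # arbitrary proper rigid motions vanish after the fit
  for (k in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, sd = 2)
    mob <- sweep(ref %*% t(R), 2, t, `+`)
    r <- kabsch_superpose(mob, ref)
    expect_lt(r$fit_rmsd, 1e-6)
    expect_equal(det(r$rotation), 1, tolerance = 1e-9)
  }
  # displace exactly one measure atom by 0.1 nm; fit atoms untouched
  n_meas <- 4
  mob <- ref
  mob[7, ] <- mob[7, ] + c(0.1, 0, 0)
  r <- kabsch_superpose(mob, ref, fit_selection = 1:6,
                        measure_selection = 7:10)
  expect_equal(r$fit_rmsd, 0, tolerance = 1e-10)
  expect_equal(r$measure_rmsd, 0.1 / sqrt(n_meas), tolerance = 1e-10)
  # degenerate fits are refused
  line <- cbind(1:5, 0, 0) * 0.1
  expect_error(kabsch_superpose(line + 0, line, 1:5), "collinear")
  expect_error(kabsch_superpose(ref, ref, 1:2), "at least 3")
})

test_that("superposed RMSD never exceeds unfitted RMSD", {
  set.seed(11)
  for (k in 1:30) {
    ref <- matrix(rnorm(24), ncol = 3)
    mob <- ref + matrix(rnorm(24, sd = 0.3), ncol = 3)
    fitted <- kabsch_superpose(mob, ref)$fit_rmsd
    raw <- sqrt(mean(rowSums((mob - ref)^2)))
    expect_lte(fitted, raw + 1e-12)
  }
})

test_that("rmsd_timeseries reports per-frame, final and mean values", {
  set.seed(3)
  ref <- matrix(rnorm(30), ncol = 3)
  # copies -> zeros; rigid motions -> ~zeros
  frames <- list(ref, sweep(ref %*% t(random_rotation()), 2, c(1, 2, 3), `+`))
  rs <- rmsd_timeseries(trajectory(frames), ref, 1:10)
  expect_lt(max(rs$rmsd), 1e-6)
  # two-frame fixture with one displaced measure atom
  mob <- ref
  mob[8, ] <- mob[8, ] + c(0, 0.1, 0)
  rs <- rmsd_timeseries(trajectory(list(ref, mob)), ref,
                        fit_selection = 1:6, measure_selection = 7:10)
  expect_equal(rs$rmsd, c(0, 0.1 / sqrt(4)), tolerance = 1e-10)
  expect_equal(rs$final, 0.1 / sqrt(4), tolerance = 1e-10)
})
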