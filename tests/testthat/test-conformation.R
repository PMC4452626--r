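# disaccharide builder, torsion measurement, classification, sampling

test_that("measure(build(phi)) round-trips across the torsion grid", {
  # coarse grid here; the fine grid belongs to the acceptance suite
  for (pa in seq(-150, 180, by = 60)) {
    for (pb in seq(-150, 180, by = 60)) {
      s <- suppressWarnings(build_disaccharide(pa, pb))
      t <- measure_glycosidic_torsions(s$coordinates, s$topology)
      expect_equal(t$phi_alpha, pa, tolerance = 1e-3)
      expect_equal(t$phi_beta, pb, tolerance = 1e-3)
    }
  }
})

test_that("built rings are 4C1 chairs with correct anomeric configurations", {
  s <- build_disaccharide(60, -60)
  co <- s$coordinates
  top <- s$topology
  for (ring in c("alpha", "beta")) {
    rt <- ring_torsions(co, top, ring)
    # alternating signs, chair-like magnitudes
    expect_true(all(sign(rt) == c(1, -1, 1, -1, 1, -1)))
    expect_true(all(abs(abs(rt) - 55) < 5))
  }
  a <- top$atoms
  ai <- function(res, nm) which(a$residue_index == res & a$name == nm)
  # anomeric impropers: alpha (O1 axial) near -120, beta (O1 equatorial) +120
  imp_a <- dihedral(co[ai(1, "O1"), ], co[ai(1, "O5"), ],
                    co[ai(1, "C1"), ], co[ai(1, "C2"), ])
  imp_b <- dihedral(co[ai(1, "O1"), ], co[ai(2, "O5"), ],
                    co[ai(2, "C1"), ], co[ai(2, "C2"), ])
  expect_lt(abs(imp_a + 120), 5)
  expect_lt(abs(imp_b - 120), 5)
  # the well-centre conformer puts H1-H1' inside the NOE-compatible range
  d <- function(i, j) sqrt(sum((co[i, ] - co[j, ])^2))
  expect_lt(d(ai(1, "H1"), ai(2, "H1")), 0.26)
  # bonded geometry sanity: ring closure within 0.01 nm of a C-O bond
  expect_lt(abs(d(ai(1, "C5"), ai(1, "O5")) - 0.143), 0.012)
  expect_lt(abs(d(ai(2, "C5"), ai(2, "O5")) - 0.143), 0.012)
})

test_that("classify_conformation pins the syn well edges", {
  expect_equal(classify_conformation(list(phi_alpha = 60, phi_beta = -60)),
               "syn-exo/syn-exo")
  expect_equal(classify_conformation(list(phi_alpha = 180, phi_beta = -60)),
               "other")
  expect_equal(classify_conformation(list(phi_alpha = 100, phi_beta = -60)),
               "other")  # exclusive upper edge
  expect_equal(classify_conformation(list(phi_alpha = 99.9, phi_beta = -60)),
               "syn-exo/syn-exo")
  expect_equal(classify_conformation(list(phi_alpha = 60, phi_beta = -100)),
               "other")
})

test_that("H1-H1' lengthens monotonically as phi_beta leaves the syn well", {
  # the separation grows monotonically from the well centre up to the cone
  # maximum near +80 deg; anti (180 deg) remains far above the well value
  dists <- vapply(seq(-60, 80, by = 20), function(pb) {
    s <- suppressWarnings(build_disaccharide(60, pb))
    a <- s$topology$atoms
    i <- which(a$residue_index == 1 & a$name == "H1")
    j <- which(a$residue_index == 2 & a$name == "H1")
    sqrt(sum((s$coordinates[i, ] - s$coordinates[j, ])^2))
  }, numeric(1))
  expect_true(all(diff(dists) > 0))
  anti <- suppressWarnings(build_disaccharide(60, 180))
  a <- anti$topology$atoms
  i <- which(a$residue_index == 1 & a$name == "H1")
  j <- which(a$residue_index == 2 & a$name == "H1")
  d_anti <- sqrt(sum((anti$coordinates[i, ] - anti$coordinates[j, ])^2))
  expect_gt(d_anti, dists[1] + 0.05)
})

test_that("sample_ensemble is seeded, centred and round-trip consistent", {
  # zero spread: identical conformers
  e0 <- sample_ensemble(c(60, -60), 0, n = 3, seed = 2)
  expect_equal(e0$trajectory$coords[1, , ], e0$trajectory$coords[3, , ])
  # same seed twice: identical ensembles
  e1 <- sample_ensemble(c(60, -60), 15, n = 20, seed = 7)
  e2 <- sample_ensemble(c(60, -60), 15, n = 20, seed = 7)
  expect_identical(e1$trajectory$coords, e2$trajectory$coords)
  expect_identical(e1$torsions, e2$torsions)
  # generating torsions match the measured ones conformer by conformer
  for (i in c(1, 7, 20)) {
    t <- measure_glycosidic_torsions(
      matrix(e1$trajectory$coords[i, , ], ncol = 3), e1$topology)
    expect_equal(t$phi_alpha, e1$torsions[i, 1], tolerance = 1e-3)
    expect_equal(t$phi_beta, e1$torsions[i, 2], tolerance = 1e-3)
  }
  # law of large numbers on the sample mean
  e3 <- sample_ensemble(c(60, -60), 15, n = 1000, seed = 11)
  expect_lt(abs(mean(e3$torsions[, 1]) - 60), 2)
  expect_lt(abs(mean(e3$torsions[, 2]) + 60), 2)
})
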