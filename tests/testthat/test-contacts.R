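# hydrogen-bond and salt-bridge detection

# minimal donor(+H)/acceptor system with prescribed D-A distance and D-H-A angle
make_dha <- function(da, angle) {
  h <- local({
    f <- function(t) {
      hp <- 0.1 * c(cos(t), sin(t), 0)
      u <- -hp; v <- c(da, 0, 0) - hp
      acos(sum(u * v) / sqrt(sum(u^2)) / sqrt(sum(v^2))) * 180 / pi - angle
    }
    t <- uniroot(f, c(1e-9, pi / 2), tol = 1e-12)$root
    0.1 * c(cos(t), sin(t), 0)
  })
  atoms <- data.frame(name = c("OG", "HG", "O1"),
                      residue_name = c("SER", "SER", "LIG"),
                      residue_index = c(1L, 1L, 2L),
                      stringsAsFactors = FALSE)
  top <- assign_donor_acceptor(
    topology(atoms, bonds = rbind(c(1L, 2L)), groups = list(ligand = 3L)))
  list(topology = top, coords = rbind(c(0, 0, 0), h, c(da, 0, 0)))
}

test_that("H-bond criteria are strict on both distance and angle", {
  s <- make_dha(0.30, 170)
  expect_equal(nrow(detect_hbonds(s$coords, s$topology)), 1)
  s <- make_dha(0.36, 170)
  expect_equal(nrow(detect_hbonds(s$coords, s$topology)), 0)
  # exactly at the angle threshold: excluded (strict >)
  s <- make_dha(0.30, 150)
  ang_exact <- angle_deg(s$coords[1, ], s$coords[2, ], s$coords[3, ])
  expect_equal(nrow(detect_hbonds(s$coords, s$topology,
                                  hbond_criteria(min_dha_angle = ang_exact))),
               0)
  # exactly at the distance threshold: excluded (strict <)
  s <- make_dha(0.35, 170)
  d_exact <- sqrt(sum((s$coords[1, ] - s$coords[3, ])^2))
  expect_equal(nrow(detect_hbonds(s$coords, s$topology,
                                  hbond_criteria(max_da_distance = d_exact))),
               0)
  # empty donor/acceptor scope is an error, distinct from zero contacts
  top_c <- topology(data.frame(name = c("C1", "C2"), residue_name = "NSE",
                               residue_index = 1:2))
  expect_error(detect_hbonds(matrix(0, 2, 3), top_c), "empty scope")
})

test_that("salt-bridge cut-off is inclusive at 0.7 nm", {
  mk <- function(d, resn = "LYS", nm = "NZ") {
    atoms <- data.frame(name = c("P", nm), residue_name = c("LIG", resn),
                        residue_index = c(1L, 2L), stringsAsFactors = FALSE)
    list(topology = topology(atoms),
         coords = rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  s <- mk(0.69)
  expect_equal(nrow(detect_salt_bridges(s$coords, s$topology)), 1)
  s <- mk(0.71, "ARG", "CZ")
  expect_equal(nrow(detect_salt_bridges(s$coords, s$topology)), 0)
  s <- mk(0.70)
  expect_equal(nrow(detect_salt_bridges(s$coords, s$topology)), 1)  # inclusive
  expect_equal(detect_salt_bridges(s$coords, s$topology)$partner, "LYS2")
})

test_that("detection matches the exhaustive oracle on planted and random systems", {
  # planted 7 + 5 decoys, 4 bridges + 2 decoys, single frame
  toy <- make_toy_complex(toy_system_spec(n_frames = 1L, seed = 3L))
  co <- frame_coords(toy$trajectory, 1)
  hb <- detect_hbonds(co, toy$topology)
  sb <- detect_salt_bridges(co, toy$topology)
  expect_equal(nrow(hb), 7)
  expect_equal(nrow(sb), 4)
  ohb <- oracle_hbonds(co, toy$topology)
  osb <- oracle_salt_bridges(co, toy$topology)
  expect_equal(nrow(hb), ohb$count)
  expect_equal(sort(paste(hb$donor, hb$hydrogen, hb$acceptor)), ohb$ids)
  expect_equal(sort(paste(sb$anion, sb$cation)), osb$ids)
  # random crowded systems
  for (seed in 1:25) {
    sys <- random_contact_system(seed)
    hb <- detect_hbonds(sys$coords, sys$topology)
    expect_equal(nrow(hb), oracle_hbonds(sys$coords, sys$topology)$count,
                 info = paste("hbond seed", seed))
    sb <- detect_salt_bridges(sys$coords, sys$topology)
    expect_equal(nrow(sb), oracle_salt_bridges(sys$coords, sys$topology)$count,
                 info = paste("salt seed", seed))
  }
})

test_that("counts are invariant under rigid motion and monotone in the cut-offs", {
  set.seed(21)
  for (seed in 1:10) {
    sys <- random_contact_system(seed)
    n0 <- nrow(detect_hbonds(sys$coords, sys$topology))
    b0 <- nrow(detect_salt_bridges(sys$coords, sys$topology))
    R <- random_rotation()
    moved <- sweep(sys$coords %*% t(R), 2, rnorm(3, sd = 3), `+`)
    expect_equal(nrow(detect_hbonds(moved, sys$topology)), n0)
    expect_equal(nrow(detect_salt_bridges(moved, sys$topology)), b0)
    # enlarging cut-offs never loses contacts
    n1 <- nrow(detect_hbonds(sys$coords, sys$topology,
                             hbond_criteria(max_da_distance = 0.5,
                                            min_dha_angle = 150)))
    expect_gte(n1, n0)
    b1 <- nrow(detect_salt_bridges(sys$coords, sys$topology,
                                   salt_bridge_criteria(max_distance = 0.9)))
    expect_gte(b1, b0)
  }
})

test_that("contact_timeseries aggregates counts, errors and occupancies", {
  s <- make_dha(0.30, 170)
  # 10 identical frames -> constant count, zero error
  traj <- trajectory(replicate(10, s$coords, simplify = FALSE))
  ts <- contact_timeseries(traj, s$topology, "hbond")
  expect_equal(ts$per_frame_counts, rep(1L, 10))
  expect_equal(ts$mean_count, 1)
  expect_equal(ts$error, 0)
  expect_equal(ts$per_partner_occupancy$occupancy, 1)
  # alternating geometry: frames where the acceptor is pulled out of range
  far <- s$coords; far[3, 1] <- 0.5
  traj <- trajectory(rep(list(s$coords, far), 5))
  ts <- contact_timeseries(traj, s$topology, "hbond")
  expect_equal(ts$mean_count, 0.5)
  expect_equal(ts$per_partner_occupancy$occupancy, 0.5)
  # planted multi-frame toy: per-frame counts equal the ledger exactly
  toy <- make_toy_complex(toy_system_spec(n_frames = 6L, seed = 8L))
  ts <- contact_timeseries(toy$trajectory, toy$topology, "hbond")
  expect_equal(ts$per_frame_counts, toy$ledger$per_frame_hbonds)
  expect_equal(ts$mean_count, mean(toy$ledger$per_frame_hbonds))
  sb <- contact_timeseries(toy$trajectory, toy$topology, "salt_bridge")
  expect_equal(sb$per_frame_counts, toy$ledger$per_frame_salt_bridges)
})

test_that("hbond_loss_on_binding compares unbound and bound totals", {
  unb <- make_toy_complex(toy_system_spec(n_hbonds_planted = 9L,
                                          n_frames = 4L, seed = 2L))
  bnd <- make_toy_complex(toy_system_spec(n_hbonds_planted = 7L,
                                          n_frames = 4L, seed = 2L))
  loss <- hbond_loss_on_binding(
    contact_timeseries(unb$trajectory, unb$topology, "hbond"),
    contact_timeseries(bnd$trajectory, bnd$topology, "hbond"))
  expect_equal(loss$loss, 2)
  expect_equal(loss$error, 0)
})
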