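# Synthetic systems with known ground truth.
#
# Three generators cover every pipeline input: (1) toy receptor-ligand
# complexes with planted hydrogen bonds and salt bridges plus near-miss
# decoys, laid out on a coarse station grid so contacts cannot arise by
# accident; (2) AR(1) interaction-energy series with prescribed means,
# noise and autocorrelation (the MD-like correlated regime); (3) the small
# deterministic file fixtures used in docs and tests.  Everything is
# seed-deterministic and margins are chosen so that frame jitter can never
# flip a detection outcome, which keeps count-recovery tests exact.

#' Specification of a planted-contact toy complex
#'
#' Planted H-bond triads satisfy d(D,A) <= 0.33 nm and angle(D,H,A) >= 170
#' deg (comfortably inside the 0.35 nm / 150 deg criteria); decoys violate
#' exactly one criterion (distance 0.37 nm, or angle 140 deg).  Salt bridges
#' are planted at 0.60-0.68 nm, decoys at 0.75 nm.  Per-frame Gaussian
#' jitter is clamped at 3 standard deviations, so the worst-case distance
#' perturbation is `2 * 3 * sqrt(3) * jitter`; generation refuses jitter
#' values that could cross the 0.02 nm distance margins.
#'
#' @param n_hbonds_planted,n_hbond_decoys,n_salt_bridges_planted,n_bridge_decoys,n_noise_atoms
#'   non-negative counts.
#' @param jitter per-coordinate Gaussian sd in nm (default 0.0015).
#' @param n_frames frames to generate.
#' @param seed RNG seed.
#' @export
toy_system_spec <- function(n_hbonds_planted = 7L, n_hbond_decoys = 5L,
                            n_salt_bridges_planted = 4L, n_bridge_decoys = 2L,
                            n_noise_atoms = 20L, jitter = 0.0015,
                            n_frames = 5L, seed = 1L) {
  stopifnot(n_hbonds_planted >= 0, n_hbond_decoys >= 0,
            n_salt_bridges_planted >= 0, n_bridge_decoys >= 0,
            n_noise_atoms >= 0, jitter >= 0, n_frames >= 1)
  if (2 * 3 * sqrt(3) * jitter >= 0.02)
    stop("toy_system_spec: jitter ", jitter,
         " could cross the 0.02 nm planted-contact margins")
  structure(list(n_hbonds_planted = as.integer(n_hbonds_planted),
                 n_hbond_decoys = as.integer(n_hbond_decoys),
                 n_salt_bridges_planted = as.integer(n_salt_bridges_planted),
                 n_bridge_decoys = as.integer(n_bridge_decoys),
                 n_noise_atoms = as.integer(n_noise_atoms),
                 jitter = jitter, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "ToySystemSpec")
}

# position of hydrogen achieving a given D-H-A angle, with D at origin and
# A on the +x axis at distance da; H at 0.1 nm from D in the xy-plane
.hbond_h_position <- function(da, target_angle) {
  f <- function(t) {
    h <- 0.1 * c(cos(t), sin(t), 0)
    angle_deg(c(0, 0, 0), h, c(da, 0, 0)) - target_angle
  }
  t <- stats::uniroot(f, c(1e-9, pi / 2), tol = 1e-12)$root
  0.1 * c(cos(t), sin(t), 0)
}

#' Generate a toy receptor-ligand complex with planted contacts
#'
#' Stations 3 nm apart each hold one planted contact, decoy, or noise atom,
#' so the only contacts in the system are the planted ones.  H-bond donors
#' sit on receptor serine-like residues, acceptors and phosphorus atoms on a
#' single ligand residue `LIG`; cations alternate between Arg CZ and Lys NZ.
#'
#' @param spec a [toy_system_spec()].
#' @return List with `topology` (groups `ligand`, `receptor`; donor/acceptor
#'   flags assigned), `trajectory` (`n_frames` jittered copies), and `ledger`
#'   (exact expected per-frame counts).
#' @export
make_toy_complex <- function(spec = toy_system_spec()) {
  stopifnot(inherits(spec, "ToySystemSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  atoms <- list()
  coords <- list()
  bonds <- list()
  resi <- 0L
  station <- 0
  next_station <- function() {
    station <<- station + 1
    # coarse grid, 3 nm spacing, far beyond every cut-off
    c(3 * (station %% 7), 3 * ((station %/% 7) %% 7), 3 * (station %/% 49))
  }
  add_atom <- function(name, residue_name, residue_index, pos,
                       charge = 0) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, residue_name = residue_name,
      residue_index = residue_index, chain = "A", charge = charge,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- pos
    length(atoms)
  }
  lig_res <- 9000L
  # --- calibration atoms, always present ---
  # one donor/acceptor pair and one phosphate/guanidinium pair, 2 nm apart
  # (far beyond every criterion): keeps zero-contact systems analyzable,
  # since the detectors distinguish an empty donor/acceptor scope (error)
  # from zero contacts (count 0)
  s <- next_station()
  d <- add_atom("OG", "SER", 8001L, s)
  h <- add_atom("HG", "SER", 8001L, s + .hbond_h_position(2.0, 170))
  add_atom("OC", "LIG", lig_res, s + c(2.0, 0, 0))
  bonds[[length(bonds) + 1L]] <- c(d, h)
  s <- next_station()
  add_atom("P", "LIG", lig_res, s, charge = -1)
  add_atom("CZ", "ARG", 8002L, s + c(2.0, 0, 0), charge = 1)
  # --- planted H-bonds and decoys ---
  n_hb_units <- spec$n_hbonds_planted + spec$n_hbond_decoys
  for (k in seq_len(n_hb_units)) {
    s <- next_station()
    planted <- k <= spec$n_hbonds_planted
    da <- if (planted) 0.30 else if (k %% 2 == 0) 0.37 else 0.30
    ang <- if (planted) 170 else if (k %% 2 == 0) 170 else 140
    resi <- resi + 1L
    d <- add_atom("OG", "SER", resi, s)
    h <- add_atom("HG", "SER", resi, s + .hbond_h_position(da, ang))
    a <- add_atom(sprintf("O%d", k), "LIG", lig_res, s + c(da, 0, 0))
    bonds[[length(bonds) + 1L]] <- c(d, h)
  }
  # --- planted salt bridges and decoys ---
  n_sb_units <- spec$n_salt_bridges_planted + spec$n_bridge_decoys
  for (k in seq_len(n_sb_units)) {
    s <- next_station()
    planted <- k <= spec$n_salt_bridges_planted
    dd <- if (planted) {
      0.60 + 0.08 * (k - 1) / max(1, spec$n_salt_bridges_planted - 1)
    } else 0.75
    p <- add_atom(sprintf("P"), "LIG", lig_res, s, charge = -1)
    if (k %% 2 == 1) {
      add_atom("CZ", "ARG", resi + k, s + c(dd, 0, 0), charge = 1)
    } else {
      add_atom("NZ", "LYS", resi + k, s + c(dd, 0, 0), charge = 1)
    }
  }
  resi <- resi + n_sb_units
  # --- inert noise atoms ---
  for (k in seq_len(spec$n_noise_atoms)) {
    s <- next_station()
    resi <- resi + 1L
    add_atom("C1", "NSE", resi, s + stats::runif(3, -0.5, 0.5))
  }
  df <- do.call(rbind, atoms)
  base <- do.call(rbind, coords)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL
  lig_idx <- which(df$residue_name == "LIG")
  rec_idx <- which(df$residue_name %in% c("SER", "ARG", "LYS"))
  top <- topology(df, bonds = bonds,
                  groups = list(ligand = lig_idx, receptor = rec_idx))
  top <- assign_donor_acceptor(top)
  # jittered frames, clamped at 3 sd so margins hold in every frame
  frames <- lapply(seq_len(spec$n_frames), function(f) {
    j <- matrix(stats::rnorm(length(base), 0, spec$jitter), ncol = 3)
    j <- pmin(pmax(j, -3 * spec$jitter), 3 * spec$jitter)
    base + j
  })
  ledger <- list(n_hbonds = spec$n_hbonds_planted,
                 n_salt_bridges = spec$n_salt_bridges_planted,
                 per_frame_hbonds = rep(spec$n_hbonds_planted, spec$n_frames),
                 per_frame_salt_bridges = rep(spec$n_salt_bridges_planted,
                                              spec$n_frames),
                 spec = spec)
  list(topology = top, trajectory = trajectory(frames), ledger = ledger)
}

#' Specification of a synthetic interaction-energy pair
#'
#' Default means mirror a ligand losing favourable interactions on leaving
#' the pocket: bound (-40, -20) vs unbound (-30, -15) kcal/mol, implying a
#' ground-truth LIE value of 0.18*(-10) + 0.09*(-5) = -2.25 kcal/mol.
#'
#' @param mean_vdw_bound,mean_el_bound,mean_vdw_unbound,mean_el_unbound kcal/mol.
#' @param noise_sd stationary sd of the AR(1) noise, kcal/mol.
#' @param autocorrelation AR(1) coefficient in `[0, 1)`.
#' @param n_frames series length.
#' @param seed RNG seed.
#' @export
energy_series_spec <- function(mean_vdw_bound = -40, mean_el_bound = -20,
                               mean_vdw_unbound = -30, mean_el_unbound = -15,
                               noise_sd = 2, autocorrelation = 0.5,
                               n_frames = 2000L, seed = 1L) {
  stopifnot(noise_sd >= 0, autocorrelation >= 0, autocorrelation < 1,
            n_frames >= 1)
  structure(list(mean_vdw_bound = mean_vdw_bound,
                 mean_el_bound = mean_el_bound,
                 mean_vdw_unbound = mean_vdw_unbound,
                 mean_el_unbound = mean_el_unbound,
                 noise_sd = noise_sd, autocorrelation = autocorrelation,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "EnergySeriesSpec")
}

.ar1 <- function(n, mean, sd, phi) {
  if (sd == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov_sd <- sd * sqrt(1 - phi^2)
  for (t in seq_len(n)[-1]) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  mean + x
}

#' Generate bound/unbound interaction-energy series with known truth
#'
#' @param spec an [energy_series_spec()].
#' @param params a [lie_parameters()] used for the attached ground truth.
#' @param n_blocks blocks for the series' error estimates.
#' @return List with `bound`, `unbound` ([energy_series()] objects) and
#'   `truth` (closed-form dG from the prescribed means).
#' @export
make_energy_series <- function(spec = energy_series_spec(),
                               params = lie_parameters(), n_blocks = 5L) {
  stopifnot(inherits(spec, "EnergySeriesSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  phi <- spec$autocorrelation
  bound <- energy_series(
    .ar1(spec$n_frames, spec$mean_vdw_bound, spec$noise_sd, phi),
    .ar1(spec$n_frames, spec$mean_el_bound, spec$noise_sd, phi), n_blocks)
  unbound <- energy_series(
    .ar1(spec$n_frames, spec$mean_vdw_unbound, spec$noise_sd, phi),
    .ar1(spec$n_frames, spec$mean_el_unbound, spec$noise_sd, phi), n_blocks)
  truth <- params$alpha * (spec$mean_vdw_bound - spec$mean_vdw_unbound) +
    params$beta * (spec$mean_el_bound - spec$mean_el_unbound)
  list(bound = bound, unbound = unbound, truth = truth, spec = spec)
}

#' Write the bundled deterministic reference fixtures
#'
#' Produces the small plain-text files used in documentation and tests: a
#' 3-atom PDB, a toy planted-contact complex (PDB structure + XYZ-table
#' trajectory + parameter table), and the two-restraint NOE table with the
#' NMR upper bounds 0.25 nm (H1-H1') and 0.35 nm (H5-H2').  Regeneration is
#' byte-identical.
#'
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
make_reference_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  # 3-atom PDB
  p <- file.path(dir, "three_atoms.pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       1.800   2.300   3.100  1.00  0.00           H",
    "ATOM      3  N   LIG A   2       4.000   5.000   6.000  1.00  0.00           N",
    "END"), p)
  out["three_atoms_pdb"] <- p
  # toy complex
  toy <- make_toy_complex(toy_system_spec())
  p <- file.path(dir, "toy_complex.pdb")
  write_pdb(list(topology = toy$topology,
                 coordinates = frame_coords(toy$trajectory, 1)), p)
  out["toy_complex_pdb"] <- p
  p <- file.path(dir, "toy_complex_traj.tsv")
  write_xyz_table(toy$trajectory, p)
  out["toy_complex_traj"] <- p
  # parameter table covering the toy complex atom types
  p <- file.path(dir, "toy_params.tsv")
  writeLines(c(
    "residue_name atom_name charge_e epsilon_kcal_mol rmin_half_nm",
    "SER OG -0.66 0.1521 0.17682",
    "SER HG 0.43 0.0460 0.02245",
    "LIG P -1.00 0.5850 0.21500",
    "ARG CZ 0.64 0.0550 0.20000",
    "LYS NZ -0.30 0.1700 0.18500",
    "NSE C1 0.00 0.0660 0.19080"), p)
  out["parameter_table"] <- p
  # NOE restraints: the two NMR upper bounds of the (1<->1) linkage
  p <- file.path(dir, "noe_restraints.tsv")
  writeLines(c("atom_a atom_b upper_bound_nm",
               "AGN.H1 BGN.H1 0.25",
               "AGN.H5 BGN.H2 0.35"), p)
  out["noe_restraints"] <- p
  out
}
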