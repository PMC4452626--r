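# Ligand-environment nonbonded energetics and LIE binding free energies.
#
# The pairwise evaluator uses a Lennard-Jones 12-6 potential with
# Lorentz-Berthelot combination (arithmetic rmin, geometric epsilon) and a
# Coulomb term, both damped by the cubic-in-r^2 switching function that
# accompanies the common 1.0-1.2 nm cut-off scheme.  Energies are kcal/mol,
# distances nm, charges elementary charges.

# Coulomb constant e^2/(4 pi eps0) in kcal nm / (mol e^2)
.K_COULOMB <- 33.2063711
# gas constant in kcal/(mol K)
.R_KCAL <- 1.9872e-3

#' Nonbonded evaluation parameters
#' @param cutoff nm; interactions vanish identically beyond it.
#' @param switch_on nm; switching starts here (must be `< cutoff`).
#' @param relative_dielectric dimensionless.
#' @export
nonbonded_params <- function(cutoff = 1.2, switch_on = 1.0,
                             relative_dielectric = 1.0) {
  stopifnot(switch_on > 0, switch_on < cutoff, relative_dielectric > 0)
  structure(list(cutoff = cutoff, switch_on = switch_on,
                 coulomb_constant = .K_COULOMB,
                 relative_dielectric = relative_dielectric),
            class = "NonbondedParams")
}

# cubic-in-r^2 switching factor, vectorised over r
switching_factor <- function(r, params) {
  s2 <- params$switch_on^2
  c2 <- params$cutoff^2
  r2 <- r * r
  f <- (c2 - r2)^2 * (c2 + 2 * r2 - 3 * s2) / (c2 - s2)^3
  out <- ifelse(r <= params$switch_on, 1, ifelse(r >= params$cutoff, 0, f))
  out
}

# vectorised core: LJ + Coulomb for parallel parameter/charge/distance vectors
.pair_energy_vec <- function(eps_i, rmin_half_i, q_i,
                             eps_j, rmin_half_j, q_j, r, params) {
  if (any(r <= 0)) stop("pair_energy: r must be > 0")
  sw <- switching_factor(r, params)
  epsij <- sqrt(eps_i * eps_j)
  rmin <- rmin_half_i + rmin_half_j
  sr6 <- (rmin / r)^6
  v_vdw <- epsij * (sr6 * sr6 - 2 * sr6) * sw
  v_el <- params$coulomb_constant * q_i * q_j /
    (params$relative_dielectric * r) * sw
  # identically zero beyond the cut-off, immune to rounding in sw
  beyond <- r >= params$cutoff
  v_vdw[beyond] <- 0
  v_el[beyond] <- 0
  list(v_vdw = v_vdw, v_el = v_el)
}

#' Nonbonded pair energy
#'
#' @param atom_i,atom_j lists or one-row data.frames with `charge` (e),
#'   `lj_epsilon` (kcal/mol) and `lj_rmin_half` (nm).
#' @param r separation in nm (> 0).
#' @param params a [nonbonded_params()].
#' @return Named numeric `c(v_vdw =, v_el =)` in kcal/mol; both exactly 0 for
#'   `r >= cutoff`.
#' @export
pair_energy <- function(atom_i, atom_j, r, params = nonbonded_params()) {
  v <- .pair_energy_vec(atom_i$lj_epsilon, atom_i$lj_rmin_half, atom_i$charge,
                        atom_j$lj_epsilon, atom_j$lj_rmin_half, atom_j$charge,
                        r, params)
  c(v_vdw = v$v_vdw, v_el = v$v_el)
}

#' Ligand-environment interaction energy of one frame
#'
#' Sums [pair_energy()] over all (ligand, non-ligand) atom pairs;
#' ligand-internal and environment-internal pairs are excluded, as required
#' for LIE averages.
#'
#' @param coords n x 3 frame coordinates (nm).
#' @param top a [topology()] with charges/LJ parameters applied.
#' @param ligand_selection 1-based atom indices; non-empty strict subset.
#' @param params a [nonbonded_params()].
#' @return Named numeric `c(v_vdw =, v_el =)` in kcal/mol.
#' @export
ligand_environment_energy <- function(coords, top, ligand_selection,
                                      params = nonbonded_params()) {
  n <- n_atoms(top)
  lig <- as.integer(ligand_selection)
  if (!length(lig)) stop("ligand_environment_energy: empty ligand selection")
  env <- setdiff(seq_len(n), lig)
  if (!length(env)) stop("ligand_environment_energy: empty environment")
  a <- top$atoms
  vv <- 0
  ve <- 0
  ce <- coords[env, , drop = FALSE]
  for (i in lig) {
    dv <- sweep(ce, 2, coords[i, ])
    r <- sqrt(rowSums(dv^2))
    keep <- r < params$cutoff
    if (!any(keep)) next
    e <- .pair_energy_vec(a$lj_epsilon[i], a$lj_rmin_half[i], a$charge[i],
                          a$lj_epsilon[env][keep], a$lj_rmin_half[env][keep],
                          a$charge[env][keep], r[keep], params)
    vv <- vv + sum(e$v_vdw)
    ve <- ve + sum(e$v_el)
  }
  c(v_vdw = vv, v_el = ve)
}

#' Interaction-energy series container
#'
#' @param v_vdw,v_el per-frame energies in kcal/mol.
#' @param n_blocks blocks for the error estimates.
#' @return An `InteractionEnergySeries`: per-frame series, means, and
#'   block-average errors.
#' @export
energy_series <- function(v_vdw, v_el, n_blocks = 5L) {
  stopifnot(length(v_vdw) == length(v_el), length(v_vdw) >= 1)
  bv <- block_error_or_zero(v_vdw, n_blocks)
  be <- block_error_or_zero(v_el, n_blocks)
  structure(list(v_vdw = v_vdw, v_el = v_el,
                 mean_vdw = mean(v_vdw), mean_el = mean(v_el),
                 err_vdw = bv$error, err_el = be$error,
                 n_blocks = n_blocks),
            class = "InteractionEnergySeries")
}

#' Ligand-surrounding energies over a trajectory
#'
#' @param traj a [trajectory()].
#' @param top the matching [topology()].
#' @param ligand_selection 1-based atom indices of the ligand.
#' @param params a [nonbonded_params()].
#' @param n_blocks blocks for errors.
#' @return An [energy_series()].
#' @export
interaction_energy_series <- function(traj, top, ligand_selection,
                                      params = nonbonded_params(),
                                      n_blocks = 5L) {
  nf <- traj$n_frames
  vv <- numeric(nf)
  ve <- numeric(nf)
  for (i in seq_len(nf)) {
    e <- ligand_environment_energy(frame_coords(traj, i), top,
                                   ligand_selection, params)
    vv[i] <- e["v_vdw"]
    ve[i] <- e["v_el"]
  }
  energy_series(vv, ve, n_blocks)
}

#' LIE parameters
#' @param alpha,beta empirical LIE coefficients (defaults 0.18 and 0.09).
#' @param temperature K.
#' @export
lie_parameters <- function(alpha = 0.18, beta = 0.09, temperature = 298) {
  stopifnot(alpha > 0, beta > 0, temperature > 0)
  structure(list(alpha = alpha, beta = beta, temperature = temperature,
                 gas_constant = .R_KCAL),
            class = "LIEParameters")
}

.RT <- function(params) params$gas_constant * params$temperature

#' LIE binding free energy
#'
#' `dG_bind = alpha * (mean V_vdw bound - unbound) + beta * (mean V_el bound -
#' unbound)`.  The unbound state is an input series (e.g. the ligand at an
#' octane-water interface); it is never re-simulated here.  The error is the
#' quadrature of the four block-average errors weighted by alpha/beta.
#'
#' @param bound,unbound [energy_series()] objects.
#' @param params a [lie_parameters()].
#' @return A `LIEResult`: list with `dg_bind`, `error`, `kd`
#'   (`exp(dG/RT)`, ratio to standard state), `delta_vdw`, `delta_el`.
#' @export
lie_free_energy <- function(bound, unbound, params = lie_parameters()) {
  stopifnot(inherits(bound, "InteractionEnergySeries"),
            inherits(unbound, "InteractionEnergySeries"))
  dvdw <- bound$mean_vdw - unbound$mean_vdw
  del <- bound$mean_el - unbound$mean_el
  dg <- params$alpha * dvdw + params$beta * del
  err <- sqrt(params$alpha^2 * (bound$err_vdw^2 + unbound$err_vdw^2) +
                params$beta^2 * (bound$err_el^2 + unbound$err_el^2))
  structure(list(dg_bind = dg, error = err,
                 kd = exp(dg / .RT(params)),
                 delta_vdw = dvdw, delta_el = del, params = params),
            class = "LIEResult")
}

#' @export
print.LIEResult <- function(x, ...) {
  cat(sprintf("LIEResult: dG_bind = %.3f +/- %.3f kcal/mol (Kd ratio %.3g)\n",
              x$dg_bind, x$error, x$kd))
  invisible(x)
}

#' Combine pose free energies by Boltzmann (exponential) averaging
#'
#' With equal pose priors,
#' `dG_comb = -RT log( mean_i exp(-dG_i / RT) )`.  The 1/N normalization
#' makes equal poses return their common value, and in general
#' `min_i dG_i <= dG_comb <= min_i dG_i + RT log N` (it is a weighted mean
#' over poses, not a sum over extra bound states).
#'
#' @param per_pose_dg named numeric of per-pose free energies (kcal/mol).
#' @param params a [lie_parameters()].
#' @return Combined free energy in kcal/mol.
#' @export
combine_poses <- function(per_pose_dg, params = lie_parameters()) {
  if (!length(per_pose_dg)) stop("combine_poses: no poses given")
  rt <- .RT(params)
  m <- min(per_pose_dg)  # subtract for numerical stability
  -rt * (log(mean(exp(-(per_pose_dg - m) / rt))) - m / rt)
}

#' Fold-difference in dissociation constant between two ligands
#'
#' `ratio = exp((dG_b - dG_a) / RT)`: how many fold more strongly ligand `a`
#' binds than ligand `b` (`> 1` iff `dG_a < dG_b`).
#'
#' @param dg_a,dg_b binding free energies in kcal/mol.
#' @param params a [lie_parameters()].
#' @export
dissociation_ratio <- function(dg_a, dg_b, params = lie_parameters()) {
  stopifnot(is.finite(dg_a), is.finite(dg_b))
  exp((dg_b - dg_a) / .RT(params))
}

#' Relative free energy between two poses
#'
#' `ddG = dG_pose_b - dG_pose_a`; positive values mean pose B is disfavored.
#'
#' @param dg_pose_a,dg_pose_b kcal/mol.
#' @export
pose_preference <- function(dg_pose_a, dg_pose_b) {
  stopifnot(is.finite(dg_pose_a), is.finite(dg_pose_b))
  dg_pose_b - dg_pose_a
}
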