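# Configuration-driven end-to-end runs producing the three report surfaces:
# a contact-occupancy table (mean H-bonds / salt bridges with block errors
# and a marker-residue RMSD), a LIE free-energy table (per-pose dG, pose
# combination, Kd fold ratios), and an NOE bound-violation table.
#
# The config is one declarative JSON file.  All numeric defaults equal the
# standard methodology values (0.35 nm / 150 deg H-bonds, 0.7 nm salt
# bridges, alpha 0.18 / beta 0.09 at 298 K, 1.0/1.2 nm switching, 5 blocks,
# 1000 ps equilibration discard), so an overrides-free run reproduces the
# reference protocol.  Every report embeds the criteria it used.

.config_error <- function(msg) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.data_error <- function(msg) {
  stop(structure(class = c("data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read a pipeline run configuration
#'
#' @param path JSON file; see the package vignette for the schema.
#' @return Config list with class `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .config_error(paste("config file not found:", path))
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    .config_error(paste("config parse error:", conditionMessage(e))))
  structure(cfg, class = "RunConfig")
}

.cfg_default <- function(cfg, name, default) {
  if (is.null(cfg[[name]])) default else cfg[[name]]
}

.load_system <- function(cfg) {
  if (is.null(cfg$structure)) .config_error("config needs 'structure'")
  if (!file.exists(cfg$structure))
    .config_error(paste("structure file not found:", cfg$structure))
  s <- read_structure(cfg$structure, .cfg_default(cfg, "structure_dialect", "pdb"))
  top <- s$topology
  if (!is.null(cfg$parameter_table)) {
    top <- apply_parameters(top, read_parameter_table(cfg$parameter_table))
  }
  # groups defined as selection expressions
  for (g in names(cfg$groups)) {
    top$groups[[g]] <- select_atoms(top, cfg$groups[[g]])
  }
  top <- assign_donor_acceptor(top)
  traj <- if (!is.null(cfg$trajectory)) {
    if (!file.exists(cfg$trajectory))
      .config_error(paste("trajectory file not found:", cfg$trajectory))
    read_trajectory(cfg$trajectory, top,
                    .cfg_default(cfg, "trajectory_dialect", "xyz-table"),
                    discard_initial = .cfg_default(cfg, "discard_initial", 1000))
  } else {
    trajectory(list(s$coordinates))
  }
  list(topology = top, trajectory = traj, reference = s$coordinates)
}

.write_report <- function(report, out_dir, stem) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the contact analysis (occupancy-table surface)
#'
#' @param config a `RunConfig` (or path to one).
#' @param out_dir output directory; reports are written as JSON/TSV.
#' @return Report list (invisibly written to `out_dir` if given).
#' @export
run_contacts <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  sys <- .load_system(config)
  n_blocks <- .cfg_default(config, "n_blocks", 5L)
  hb_cfg <- config$hbond_criteria
  hb <- hbond_criteria(
    max_da_distance = if (is.null(hb_cfg$max_da_distance)) 0.35 else hb_cfg$max_da_distance,
    min_dha_angle = if (is.null(hb_cfg$min_dha_angle)) 150 else hb_cfg$min_dha_angle)
  sb_cfg <- config$salt_bridge_criteria
  sb <- salt_bridge_criteria(
    max_distance = if (is.null(sb_cfg$max_distance)) 0.7 else sb_cfg$max_distance)
  scope <- .cfg_default(config, "scope", "ligand-all")
  if (is.null(sys$topology$groups[["ligand"]]) && scope != "all")
    .config_error("contacts: no 'ligand' group defined")
  hbs <- contact_timeseries(sys$trajectory, sys$topology, "hbond",
                            criteria = hb, scope = scope, n_blocks = n_blocks)
  sbs <- contact_timeseries(sys$trajectory, sys$topology, "salt_bridge",
                            criteria = sb, n_blocks = n_blocks)
  if (sys$trajectory$n_frames == 1)
    warning("run_contacts: single frame; block errors reported as 0")
  report <- list(
    criteria = list(hbond = unclass(hb), salt_bridge = unclass(sb),
                    scope = scope, n_blocks = n_blocks),
    hbonds = list(mean = hbs$mean_count, error = hbs$error,
                  per_frame = hbs$per_frame_counts,
                  occupancy = hbs$per_partner_occupancy),
    salt_bridges = list(mean = sbs$mean_count, error = sbs$error,
                        per_frame = sbs$per_frame_counts,
                        occupancy = sbs$per_partner_occupancy))
  # optional marker-residue RMSD after rotational fit
  if (!is.null(config$rmsd)) {
    fit <- select_atoms(sys$topology, config$rmsd$fit_selection)
    mea <- select_atoms(sys$topology, config$rmsd$measure_selection)
    rs <- rmsd_timeseries(sys$trajectory, sys$reference, fit, mea)
    report$marker_rmsd <- list(fit_selection = config$rmsd$fit_selection,
                               measure_selection = config$rmsd$measure_selection,
                               final_nm = rs$final, mean_nm = rs$mean,
                               series_nm = rs$rmsd)
  }
  if (!is.null(out_dir)) {
    .write_report(report, out_dir, "contacts")
    utils::write.table(
      report$hbonds$occupancy, file.path(out_dir, "hbond_occupancy.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      report$salt_bridges$occupancy,
      file.path(out_dir, "salt_bridge_occupancy.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Read an interaction-energy series TSV (`frame v_vdw_kcal v_el_kcal`)
#' @param path file path.
#' @param n_blocks blocks for the error estimate.
#' @export
read_energy_series <- function(path, n_blocks = 5L) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("v_vdw_kcal", "v_el_kcal")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("energy series table missing columns: ",
                         paste(miss, collapse = ", "))
  energy_series(df$v_vdw_kcal, df$v_el_kcal, n_blocks)
}

#' Write an interaction-energy series TSV
#' @param series an [energy_series()].
#' @param path output file.
#' @export
write_energy_series <- function(series, path) {
  df <- data.frame(frame = seq_along(series$v_vdw),
                   v_vdw_kcal = series$v_vdw, v_el_kcal = series$v_el)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the LIE analysis (free-energy-table surface)
#'
#' Config schema: `poses` is a named map, each pose holding `bound` and
#' `unbound` energy-series TSV paths; optional `lie` overrides
#' (`alpha`, `beta`, `temperature`); optional `reference_dg` (kcal/mol) for
#' Kd fold-ratio reporting.
#'
#' @param config a `RunConfig` or path.
#' @param out_dir optional output directory.
#' @return Report list.
#' @export
run_lie <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$poses) || !length(config$poses))
    .config_error("lie: config needs a non-empty 'poses' map")
  lp <- lie_parameters(
    alpha = .cfg_default(config$lie, "alpha", 0.18),
    beta = .cfg_default(config$lie, "beta", 0.09),
    temperature = .cfg_default(config$lie, "temperature", 298))
  n_blocks <- .cfg_default(config, "n_blocks", 5L)
  per_pose <- list()
  for (pose in names(config$poses)) {
    pc <- config$poses[[pose]]
    if (is.null(pc$bound) || is.null(pc$unbound))
      .config_error(paste0("lie: pose '", pose,
                           "' needs both bound and unbound series ",
                           "(LIE is a two-state estimate)"))
    for (f in c(pc$bound, pc$unbound))
      if (!file.exists(f)) .data_error(paste("series file not found:", f))
    r <- lie_free_energy(read_energy_series(pc$bound, n_blocks),
                         read_energy_series(pc$unbound, n_blocks), lp)
    per_pose[[pose]] <- list(dg_bind = r$dg_bind, error = r$error,
                             delta_vdw = r$delta_vdw, delta_el = r$delta_el)
  }
  dgs <- vapply(per_pose, `[[`, numeric(1), "dg_bind")
  combined <- combine_poses(dgs, lp)
  report <- list(parameters = list(alpha = lp$alpha, beta = lp$beta,
                                   temperature = lp$temperature,
                                   n_blocks = n_blocks),
                 per_pose = per_pose,
                 combined_dg = combined)
  if (length(dgs) >= 2)
    report$ddg_pose_b_vs_a <- pose_preference(dgs[[1]], dgs[[2]])
  if (!is.null(config$reference_dg))
    report$kd_fold_vs_reference <- dissociation_ratio(combined,
                                                      config$reference_dg, lp)
  if (!is.null(out_dir)) .write_report(report, out_dir, "lie")
  invisible(report)
}

#' Run the NOE analysis (bound-violation surface)
#'
#' The ensemble comes either from a multi-MODEL PDB (`ensemble` path, atom
#' naming as in [build_disaccharide()]) or from the torsion sampler
#' (`sample`: `center`, `spread_deg`, `n`, with the run seed).
#'
#' @param config a `RunConfig` or path.
#' @param out_dir optional output directory.
#' @param seed RNG seed used when sampling an ensemble.
#' @return Report list.
#' @export
run_noe <- function(config, out_dir = NULL, seed = 1L) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$restraints))
    .config_error("noe: config needs 'restraints'")
  if (!file.exists(config$restraints))
    .config_error(paste("restraints file not found:", config$restraints))
  restraints <- read_noe_restraints(config$restraints)
  n_blocks <- .cfg_default(config, "n_blocks", 5L)
  if (!is.null(config$ensemble)) {
    first <- read_structure(config$ensemble, "pdb")
    top <- suppressWarnings(first$topology)
    traj <- read_trajectory(config$ensemble, top, "pdb", discard_initial = 0)
  } else if (!is.null(config$sample)) {
    sc <- config$sample
    ens <- sample_ensemble(center = .cfg_default(sc, "center", c(60, -60)),
                           spread_deg = .cfg_default(sc, "spread_deg", 15),
                           n = .cfg_default(sc, "n", 1000L), seed = seed)
    top <- ens$topology
    traj <- ens$trajectory
  } else {
    .config_error("noe: config needs 'ensemble' or 'sample'")
  }
  if (!nrow(restraints)) {
    warning("run_noe: empty restraint table; empty report")
    report <- list(results = list(), max_violation = 0, n_violated = 0)
  } else {
    rep0 <- tryCatch(violation_report(traj, top, restraints, n_blocks),
                     error = function(e) .data_error(conditionMessage(e)))
    report <- list(results = rep0$results, max_violation = rep0$max_violation,
                   n_violated = rep0$n_violated, n_blocks = n_blocks)
  }
  if (!is.null(out_dir)) {
    .write_report(report, out_dir, "noe")
    if (length(report$results))
      utils::write.table(report$results, file.path(out_dir, "noe_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
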