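# File I/O: PDB structures and multi-MODEL trajectories, a flat per-frame XYZ
# table (the native trajectory dialect), whitespace-delimited nonbonded
# parameter tables, and NOE restraint tables.
#
# PDB coordinates are Angstrom on disk and converted to nm (factor 0.1) on
# read; the reverse on write.  Only fixed-column ATOM/HETATM/MODEL/ENDMDL/
# CONECT records are interpreted.

.ANG_PER_NM <- 10

.parse_pdb_atom_line <- function(line, lineno) {
  get <- function(a, b) trimws(substr(line, a, b))
  serial <- suppressWarnings(as.integer(get(7, 11)))
  x <- suppressWarnings(as.numeric(get(31, 38)))
  y <- suppressWarnings(as.numeric(get(39, 46)))
  z <- suppressWarnings(as.numeric(get(47, 54)))
  resi <- suppressWarnings(as.integer(get(23, 26)))
  if (anyNA(c(serial, x, y, z, resi)))
    stop(sprintf("PDB parse error at line %d: %s", lineno, line))
  list(serial = serial, name = get(13, 16), residue_name = get(18, 20),
       chain = if (nzchar(get(22, 22))) get(22, 22) else "A",
       residue_index = resi, x = x, y = y, z = z,
       element = get(77, 78))
}

.read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- list()
  conect <- list()
  for (i in seq_along(lines)) {
    r <- trimws(rec[i])
    if (r %in% c("ATOM", "HETATM")) {
      cur[[length(cur) + 1L]] <- .parse_pdb_atom_line(lines[i], i)
    } else if (r == "ENDMDL") {
      models[[length(models) + 1L]] <- cur
      cur <- list()
    } else if (r == "CONECT") {
      f <- suppressWarnings(as.integer(strsplit(trimws(substr(lines[i], 7, 80)),
                                                "\\s+")[[1]]))
      if (length(f) >= 2 && !anyNA(f))
        conect[[length(conect) + 1L]] <- f
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- cur
  if (!length(models)) stop("PDB file contains no ATOM/HETATM records: ", path)
  list(models = models, conect = conect)
}

.model_to_df <- function(model) {
  df <- data.frame(
    serial = vapply(model, `[[`, integer(1), "serial"),
    name = vapply(model, `[[`, character(1), "name"),
    residue_name = vapply(model, `[[`, character(1), "residue_name"),
    chain = vapply(model, `[[`, character(1), "chain"),
    residue_index = vapply(model, `[[`, integer(1), "residue_index"),
    element = vapply(model, `[[`, character(1), "element"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$serial))
    stop("PDB parse error: duplicate atom serial number ",
         df$serial[anyDuplicated(df$serial)])
  xyz <- cbind(vapply(model, `[[`, numeric(1), "x"),
               vapply(model, `[[`, numeric(1), "y"),
               vapply(model, `[[`, numeric(1), "z")) / .ANG_PER_NM
  blank <- !nzchar(df$element)
  df$element[blank] <- .element_from_name(df$name[blank])
  list(atoms = df, coords = xyz)
}

#' Read a molecular structure
#'
#' Supported dialects: standard single- or multi-MODEL `pdb` (only the first
#' model is kept, with a warning if more are present) and the package's flat
#' `xyz-table` (header line `atom_index name residue_name residue_index chain
#' x y z`, whitespace-delimited, coordinates already in nm).
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"xyz-table"`.
#' @return A `Structure`: list with `topology` and `coordinates` (n x 3, nm).
#' @export
read_structure <- function(path, dialect = c("pdb", "xyz-table")) {
  dialect <- match.arg(dialect)
  if (dialect == "pdb") {
    parsed <- .read_pdb_models(path)
    if (length(parsed$models) > 1)
      warning(sprintf("read_structure: %d MODEL records in '%s'; keeping the first",
                      length(parsed$models), path))
    m <- .model_to_df(parsed$models[[1]])
    serial_map <- match(seq_len(max(m$atoms$serial)), m$atoms$serial)
    bonds <- NULL
    if (length(parsed$conect)) {
      pairs <- do.call(rbind, lapply(parsed$conect, function(f) {
        cbind(f[1], f[-1])
      }))
      pairs <- cbind(serial_map[pairs[, 1]], serial_map[pairs[, 2]])
      pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
      pairs <- t(apply(pairs, 1, sort))
      bonds <- unique(pairs)
    }
    atoms <- m$atoms[, c("name", "residue_name", "residue_index", "chain",
                         "element")]
    top <- topology(atoms, bonds = bonds)
    structure(list(topology = top, coordinates = m$coords),
              class = "Structure")
  } else {
    df <- tryCatch(
      utils::read.table(path, header = TRUE, stringsAsFactors = FALSE),
      error = function(e) stop("xyz-table parse error in '", path, "': ",
                               conditionMessage(e)))
    req <- c("atom_index", "name", "residue_name", "residue_index",
             "chain", "x", "y", "z")
    miss <- setdiff(req, names(df))
    if (length(miss)) stop("xyz-table missing columns: ",
                           paste(miss, collapse = ", "))
    if (anyDuplicated(df$atom_index))
      stop("xyz-table: duplicate atom_index")
    df <- df[order(df$atom_index), ]
    top <- topology(df[, c("name", "residue_name", "residue_index", "chain")])
    structure(list(topology = top,
                   coordinates = as.matrix(df[, c("x", "y", "z")])),
              class = "Structure")
  }
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure of", n_atoms(x$topology), "atoms\n")
  invisible(x)
}

.format_pdb_atom <- function(i, name, resn, chain, resi, xyz, element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i, nm, substr(resn, 1, 3), substr(chain, 1, 1), resi,
          xyz[1] * .ANG_PER_NM, xyz[2] * .ANG_PER_NM, xyz[3] * .ANG_PER_NM,
          1, 0, substr(element, 1, 2))
}

#' Write a structure or trajectory as PDB
#'
#' Multi-frame input produces a multi-MODEL file.  Bonds, if present, are
#' written as CONECT records (single-frame output only).
#'
#' @param x a `Structure` or a list(topology=, trajectory=).
#' @param path output file.
#' @export
write_pdb <- function(x, path) {
  top <- x$topology
  a <- top$atoms
  frames <- if (!is.null(x$coordinates)) list(x$coordinates)
            else lapply(seq_len(x$trajectory$n_frames),
                        function(i) frame_coords(x$trajectory, i))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1
  for (f in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    co <- frames[[f]]
    for (i in seq_len(nrow(a))) {
      writeLines(.format_pdb_atom(i, a$name[i], a$residue_name[i], a$chain[i],
                                  a$residue_index[i], co[i, ], a$element[i]),
                 con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  if (!multi && !is.null(top$bonds) && nrow(top$bonds)) {
    for (k in seq_len(nrow(top$bonds)))
      writeLines(sprintf("CONECT%5d%5d", top$bonds[k, 1], top$bonds[k, 2]),
                 con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Dialects: multi-MODEL `pdb`, or the native flat `xyz-table` with header
#' `frame atom_index x y z` (whitespace-delimited, nm; optional `time_ps`
#' column).  Frame times default to `0, 1, 2, ... ps`; frames with
#' `time < discard_initial` are dropped at load time (the usual equilibration
#' discard).
#'
#' @param path file path.
#' @param topology the matching [topology()]; atom counts are checked per
#'   frame.
#' @param dialect `"pdb"` or `"xyz-table"`.
#' @param discard_initial ps; frames strictly before this time are dropped.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology, dialect = c("pdb", "xyz-table"),
                            discard_initial = 0) {
  dialect <- match.arg(dialect)
  na <- n_atoms(topology)
  if (dialect == "pdb") {
    parsed <- .read_pdb_models(path)
    frames <- lapply(seq_along(parsed$models), function(i) {
      m <- .model_to_df(parsed$models[[i]])
      if (nrow(m$atoms) != na)
        stop(sprintf("read_trajectory: frame %d has %d atoms, topology has %d",
                     i, nrow(m$atoms), na))
      m$coords
    })
    times <- seq_along(frames) - 1
  } else {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    req <- c("frame", "atom_index", "x", "y", "z")
    miss <- setdiff(req, names(df))
    if (length(miss)) stop("xyz-table missing columns: ",
                           paste(miss, collapse = ", "))
    fr_ids <- sort(unique(df$frame))
    frames <- lapply(seq_along(fr_ids), function(k) {
      sub <- df[df$frame == fr_ids[k], ]
      if (nrow(sub) != na)
        stop(sprintf("read_trajectory: frame %d has %d atoms, topology has %d",
                     fr_ids[k], nrow(sub), na))
      sub <- sub[order(sub$atom_index), ]
      as.matrix(sub[, c("x", "y", "z")])
    })
    times <- if ("time_ps" %in% names(df)) {
      vapply(fr_ids, function(f) df$time_ps[df$frame == f][1], numeric(1))
    } else {
      seq_along(frames) - 1
    }
  }
  keep <- times >= discard_initial
  if (!any(keep)) stop("read_trajectory: discard_initial removed every frame")
  trajectory(frames[keep], times = times[keep])
}

#' Write a trajectory as the flat XYZ table dialect
#' @param traj a [trajectory()] object.
#' @param path output file.
#' @export
write_xyz_table <- function(traj, path) {
  nf <- traj$n_frames
  na <- dim(traj$coords)[2]
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom_index = rep(seq_len(na), times = nf),
    time_ps = rep(traj$times, each = na),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])))
  utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a nonbonded parameter table
#'
#' Whitespace-delimited with header
#' `residue_name atom_name charge_e epsilon_kcal_mol rmin_half_nm`, keyed by
#' (residue_name, atom_name).  PDB files carry no charges or LJ parameters,
#' so these are supplied separately; this also leaves contested chemistry
#' (e.g. phosphate protonation states) explicitly in the user's hands.
#'
#' @param path file path.
#' @return data.frame of parameters.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("residue_name", "atom_name", "charge_e", "epsilon_kcal_mol",
           "rmin_half_nm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("parameter table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$epsilon_kcal_mol < 0))
    stop("parameter table: epsilon must be >= 0")
  df
}

#' Apply a parameter table to a topology
#'
#' @param top a [topology()] object.
#' @param params data.frame from [read_parameter_table()].
#' @param strict error on atoms without a matching parameter entry (default
#'   leaves them at zero charge/LJ).
#' @return Topology with `charge`, `lj_epsilon`, `lj_rmin_half` filled in.
#' @export
apply_parameters <- function(top, params, strict = FALSE) {
  key <- paste(top$atoms$residue_name, top$atoms$name)
  pkey <- paste(params$residue_name, params$atom_name)
  hit <- match(key, pkey)
  if (strict && anyNA(hit))
    stop("apply_parameters: no parameters for ",
         paste(unique(key[is.na(hit)]), collapse = ", "))
  ok <- !is.na(hit)
  top$atoms$charge[ok] <- params$charge_e[hit[ok]]
  top$atoms$lj_epsilon[ok] <- params$epsilon_kcal_mol[hit[ok]]
  top$atoms$lj_rmin_half[ok] <- params$rmin_half_nm[hit[ok]]
  top
}

#' Read an NOE restraint table
#'
#' Whitespace-delimited with header `atom_a atom_b upper_bound_nm`.  Atom
#' names may be plain (`H1`, unique in the topology) or qualified as
#' `RES.NAME` / `RES:NAME` (residue name or index, e.g. `AGN.H1`, `2:H1`).
#'
#' @param path file path.
#' @return data.frame of restraints with positive upper bounds.
#' @export
read_noe_restraints <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("atom_a", "atom_b", "upper_bound_nm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("NOE restraint table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$upper_bound_nm <= 0))
    stop("NOE restraint table: upper bounds must be > 0")
  df
}
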