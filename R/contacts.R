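# Hydrogen-bond and salt-bridge detection with occupancy statistics.
#
# Criteria follow the common geometric definitions for MD post-processing:
# an H-bond requires donor-acceptor distance < 0.35 nm AND
# donor-hydrogen-acceptor angle > 150 deg (both strict); a phosphate salt
# bridge requires the central phosphorus to be within 0.7 nm (inclusive) of
# Arg CZ or Lys NZ.  No periodic-boundary imaging is applied: the analysis
# assumes whole, imaged complexes, which holds for a ligand buried in a
# receptor pocket and for all synthetic systems generated by this package.

#' Hydrogen-bond criteria
#' @param max_da_distance donor-acceptor cut-off in nm (strict `<`).
#' @param min_dha_angle donor-hydrogen-acceptor angle in degrees (strict `>`).
#' @export
hbond_criteria <- function(max_da_distance = 0.35, min_dha_angle = 150) {
  stopifnot(max_da_distance > 0, max_da_distance < 1,
            min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle),
            class = "HBondCriteria")
}

#' Salt-bridge criteria
#' @param max_distance cut-off in nm (inclusive `<=`).
#' @param anion_atom_names atom names treated as the anionic centre (default
#'   the central phosphorus `P` of a phosphate).
#' @param cation_atom_specs data.frame(residue_name, atom_name) of cationic
#'   centres; defaults to Arg CZ and Lys NZ.
#' @export
salt_bridge_criteria <- function(max_distance = 0.7,
                                 anion_atom_names = "P",
                                 cation_atom_specs = data.frame(
                                   residue_name = c("ARG", "LYS"),
                                   atom_name = c("CZ", "NZ"))) {
  stopifnot(max_distance > 0, length(anion_atom_names) >= 1,
            nrow(cation_atom_specs) >= 1)
  structure(list(max_distance = max_distance,
                 anion_atom_names = anion_atom_names,
                 cation_atom_specs = cation_atom_specs),
            class = "SaltBridgeCriteria")
}

.res_label <- function(atoms, i) {
  sprintf("%s%d", atoms$residue_name[i], atoms$residue_index[i])
}

.same_residue <- function(atoms, i, j) {
  atoms$residue_index[i] == atoms$residue_index[j] &
    atoms$chain[i] == atoms$chain[j]
}

.scope_pair_ok <- function(top, scope, i, j) {
  # returns logical vector: is the (i[k], j[k]) pair inside the scope
  if (scope == "all") return(rep(TRUE, length(i)))
  lig <- top$groups[["ligand"]]
  if (is.null(lig)) stop("scope '", scope, "' needs a 'ligand' group")
  in_lig_i <- i %in% lig
  in_lig_j <- j %in% lig
  if (scope == "ligand-all") return(xor(in_lig_i, in_lig_j))
  rec <- top$groups[["receptor"]]
  if (is.null(rec)) stop("scope 'ligand-protein' needs a 'receptor' group")
  (in_lig_i & (j %in% rec)) | (in_lig_j & (i %in% rec))
}

#' Detect hydrogen bonds in one frame
#'
#' A donor-hydrogen-acceptor triple is reported iff the donor-acceptor
#' distance is strictly below `max_da_distance` and the D-H-A angle is
#' strictly above `min_dha_angle`.  The distance criterion uses the donor
#' heavy atom, not the hydrogen.  Intra-residue pairs are excluded by
#' default.
#'
#' @param coords n x 3 frame coordinates (nm).
#' @param top a [topology()] with donor/acceptor flags (see
#'   [assign_donor_acceptor()]) and H-heavy bonds.
#' @param criteria an [hbond_criteria()].
#' @param scope `"ligand-all"` (ligand with protein and solvent),
#'   `"ligand-protein"`, or `"all"`.
#' @param exclude_intra_residue drop donor/acceptor in the same residue.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance`, `angle`, `id` (stable partner label).
#' @export
detect_hbonds <- function(coords, top, criteria = hbond_criteria(),
                          scope = c("ligand-all", "ligand-protein", "all"),
                          exclude_intra_residue = TRUE) {
  scope <- match.arg(scope)
  a <- top$atoms
  donors <- which(a$is_donor_heavy)
  acceptors <- which(a$is_acceptor)
  if (!length(donors) || !length(acceptors))
    stop("detect_hbonds: topology has no flagged donors or acceptors in scope ",
         "(empty scope, not zero contacts)")
  hyd <- .bonded_hydrogens(top)
  out <- list()
  for (d in donors) {
    hs <- hyd[[d]]
    if (!length(hs)) next
    acc <- acceptors[acceptors != d]
    if (exclude_intra_residue) acc <- acc[!.same_residue(a, d, acc)]
    acc <- acc[.scope_pair_ok(top, scope, rep(d, length(acc)), acc)]
    if (!length(acc)) next
    dv <- sweep(coords[acc, , drop = FALSE], 2, coords[d, ])
    da <- sqrt(rowSums(dv^2))
    acc <- acc[da < criteria$max_da_distance]
    da <- da[da < criteria$max_da_distance]
    if (!length(acc)) next
    for (h in hs) {
      ang <- vapply(seq_along(acc), function(k)
        angle_deg(coords[d, ], coords[h, ], coords[acc[k], ]), numeric(1))
      hit <- ang > criteria$min_dha_angle
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          donor = d, hydrogen = h, acceptor = acc[hit],
          distance = da[hit], angle = ang[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), distance = numeric(0),
               angle = numeric(0))
  res$id <- if (nrow(res)) {
    sprintf("%s:%s>%s:%s",
            .res_label(a, res$donor), a$name[res$donor],
            .res_label(a, res$acceptor), a$name[res$acceptor])
  } else character(0)
  res
}

#' Detect phosphate salt bridges in one frame
#'
#' A pair is reported iff the anion-cation distance is within `max_distance`
#' (inclusive).  Pairs carry the cation residue identity (e.g. `LYS122`) for
#' per-partner occupancy reporting.
#'
#' @param coords n x 3 frame coordinates (nm).
#' @param top a [topology()] object.
#' @param criteria a [salt_bridge_criteria()].
#' @return data.frame with `anion`, `cation`, `distance`, `partner`, `id`.
#' @export
detect_salt_bridges <- function(coords, top,
                                criteria = salt_bridge_criteria()) {
  a <- top$atoms
  anions <- which(a$name %in% criteria$anion_atom_names)
  spec <- criteria$cation_atom_specs
  cations <- which(paste(a$residue_name, a$name) %in%
                     paste(spec$residue_name, spec$atom_name))
  if (!length(anions) || !length(cations))
    stop("detect_salt_bridges: no anion or cation atoms resolvable in scope ",
         "(empty scope, not zero contacts)")
  out <- list()
  for (p in anions) {
    dv <- sweep(coords[cations, , drop = FALSE], 2, coords[p, ])
    dd <- sqrt(rowSums(dv^2))
    hit <- dd <= criteria$max_distance
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        anion = p, cation = cations[hit], distance = dd[hit],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(anion = integer(0), cation = integer(0), distance = numeric(0))
  res$partner <- if (nrow(res)) .res_label(a, res$cation) else character(0)
  res$id <- if (nrow(res)) {
    sprintf("%s:%s>%s:%s", .res_label(a, res$anion), a$name[res$anion],
            res$partner, a$name[res$cation])
  } else character(0)
  res
}

#' Per-frame contact counts with block-averaged uncertainty
#'
#' Runs a detector over every frame and aggregates: per-frame counts, their
#' mean and block-average error, and the occupancy (fraction of frames) of
#' every distinct contact identity, ranked by occupancy.
#'
#' @param traj a [trajectory()].
#' @param top the matching [topology()].
#' @param detector `"hbond"`, `"salt_bridge"`, or a function
#'   `(coords, top, ...)` returning a data.frame with an `id` column.
#' @param ... passed to the detector (criteria, scope, ...).
#' @param n_blocks blocks for the error estimate (default 5).
#' @return A `ContactTimeSeries`: list with `per_frame_counts`, `mean_count`,
#'   `error`, `n_blocks`, `per_partner_occupancy` (data.frame, descending).
#' @export
contact_timeseries <- function(traj, top, detector = "hbond", ...,
                               n_blocks = 5L) {
  fn <- if (is.function(detector)) detector
        else switch(detector,
                    hbond = detect_hbonds,
                    salt_bridge = detect_salt_bridges,
                    stop("unknown detector: ", detector))
  nf <- traj$n_frames
  counts <- integer(nf)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    hits <- fn(frame_coords(traj, i), top, ...)
    counts[i] <- nrow(hits)
    for (id in unique(hits$id)) {
      prev <- if (is.null(seen[[id]])) 0L else seen[[id]]
      seen[[id]] <- prev + 1L
    }
  }
  be <- block_error_or_zero(counts, n_blocks)
  ids <- ls(seen)
  occ <- if (length(ids)) {
    o <- data.frame(id = ids,
                    occupancy = vapply(ids, function(k) seen[[k]],
                                       integer(1)) / nf,
                    stringsAsFactors = FALSE, row.names = NULL)
    o[order(-o$occupancy, o$id), , drop = FALSE]
  } else {
    data.frame(id = character(0), occupancy = numeric(0))
  }
  structure(list(per_frame_counts = counts, mean_count = mean(counts),
                 error = be$error, n_blocks = be$n_blocks,
                 per_partner_occupancy = occ),
            class = "ContactTimeSeries")
}

#' Average loss of hydrogen bonds upon binding
#'
#' Difference of the mean total H-bond counts between an unbound reference
#' simulation (ligand in pure water or at an octane-water interface, solvent
#' partners included) and the receptor-bound simulation.  Positive values
#' mean bonds are lost on binding; the error combines both block errors in
#' quadrature.
#'
#' @param unbound,bound `ContactTimeSeries` of total H-bond counts.
#' @return List with `loss` and `error`.
#' @export
hbond_loss_on_binding <- function(unbound, bound) {
  stopifnot(inherits(unbound, "ContactTimeSeries"),
            inherits(bound, "ContactTimeSeries"))
  list(loss = unbound$mean_count - bound$mean_count,
       error = sqrt(unbound$error^2 + bound$error^2))
}

#' @export
print.ContactTimeSeries <- function(x, ...) {
  cat(sprintf("ContactTimeSeries: mean %.3f +/- %.3f over %d frames, %d partners\n",
              x$mean_count, x$error, length(x$per_frame_counts),
              nrow(x$per_partner_occupancy)))
  invisible(x)
}
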