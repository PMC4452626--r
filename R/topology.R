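# Topology and Trajectory containers.
#
# Conventions: all lengths are nm internally (PDB I/O converts Angstrom <-> nm
# at the boundary); atom indices are R-native 1-based both in the API and in
# file output.

.element_from_name <- function(name) {
  # strip digits/primes, first remaining letter; two-letter elements are not
  # needed for the systems handled here (C/N/O/P/S/H)
  core <- gsub("[0-9']", "", name)
  toupper(substr(core, 1, 1))
}

#' Construct a molecular topology
#'
#' @param atoms data.frame with columns `name`, `residue_name`,
#'   `residue_index`; optional `chain`, `element`, `charge`, `lj_epsilon`
#'   (kcal/mol), `lj_rmin_half` (nm), `is_donor_heavy`, `is_acceptor`.
#'   Missing optional columns are filled with defaults (element inferred from
#'   the atom name, zero charges/LJ, donor/acceptor flags unset).
#' @param bonds two-column integer matrix of 1-based atom indices (optional).
#' @param groups named list of integer vectors: named selections such as
#'   `ligand`, `receptor`, `solvent`, `CA_backbone` (optional).
#' @return A `Topology` object.
#' @export
topology <- function(atoms, bonds = NULL, groups = list()) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "residue_name", "residue_index")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("topology: missing atom columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (any(!nzchar(atoms$name))) stop("topology: atom names must be non-empty")
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$name)
  for (col in c("charge", "lj_epsilon", "lj_rmin_half")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- 0
  }
  if (any(atoms$lj_epsilon < 0)) stop("topology: lj_epsilon must be >= 0")
  for (col in c("is_donor_heavy", "is_acceptor")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  }
  atoms$index <- seq_len(n)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > n))
      stop("topology: bond endpoints outside atom range")
  }
  if (length(groups)) {
    for (g in names(groups)) {
      gi <- groups[[g]]
      if (length(gi) && (min(gi) < 1 || max(gi) > n))
        stop("topology: group '", g, "' references invalid atom indices")
      groups[[g]] <- as.integer(sort(gi))
    }
  }
  structure(list(atoms = atoms, bonds = bonds, groups = groups),
            class = "Topology")
}

#' Number of atoms in a topology
#' @param top a [topology()] object.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, %d bonds, groups: %s\n",
              n_atoms(x),
              length(unique(paste(x$atoms$chain, x$atoms$residue_index))),
              if (is.null(x$bonds)) 0L else nrow(x$bonds),
              if (length(x$groups)) paste(names(x$groups), collapse = ", ")
              else "(none)"))
  invisible(x)
}

# indices of hydrogens bonded to each heavy atom, as a list keyed by atom index
.bonded_hydrogens <- function(top) {
  out <- vector("list", n_atoms(top))
  if (is.null(top$bonds) || !nrow(top$bonds)) return(out)
  isH <- top$atoms$element == "H"
  for (k in seq_len(nrow(top$bonds))) {
    i <- top$bonds[k, 1]; j <- top$bonds[k, 2]
    if (isH[j] && !isH[i]) out[[i]] <- c(out[[i]], j)
    if (isH[i] && !isH[j]) out[[j]] <- c(out[[j]], i)
  }
  out
}

#' Assign hydrogen-bond donor/acceptor flags from elements and bonds
#'
#' Acceptors are all N and O atoms; donor heavy atoms are N or O covalently
#' bonded to at least one hydrogen (bond list required).  This element-based
#' rule is the minimal defensible reading of a purely geometric H-bond
#' criterion.
#'
#' @param top a [topology()] object with bonds.
#' @return The topology with `is_donor_heavy` / `is_acceptor` filled in.
#' @export
assign_donor_acceptor <- function(top) {
  el <- top$atoms$element
  top$atoms$is_acceptor <- el %in% c("N", "O")
  hyd <- .bonded_hydrogens(top)
  has_h <- vapply(hyd, function(h) length(h) > 0, logical(1))
  top$atoms$is_donor_heavy <- top$atoms$is_acceptor & has_h
  top
}

#' Infer covalent bonds to hydrogens from distances (opt-in fallback)
#'
#' Connects every hydrogen to all heavy atoms within `cutoff` (default
#' 0.18 nm).  Only intended for structures that lack explicit connectivity;
#' its use is reported via `message()`.
#'
#' @param top a [topology()] object.
#' @param coords n x 3 coordinates (nm).
#' @param cutoff nm.
#' @return Topology with the inferred H-heavy bonds appended.
#' @export
infer_h_bonds_from_distance <- function(top, coords, cutoff = 0.18) {
  isH <- top$atoms$element == "H"
  hs <- which(isH)
  heavies <- which(!isH)
  new <- list()
  for (h in hs) {
    d2 <- rowSums(sweep(coords[heavies, , drop = FALSE], 2, coords[h, ])^2)
    near <- heavies[d2 < cutoff^2]
    if (length(near)) new[[length(new) + 1L]] <- cbind(near, h)
  }
  nb <- if (length(new)) do.call(rbind, new) else NULL
  message(sprintf("infer_h_bonds_from_distance: inferred %d H-heavy bonds (cutoff %.2f nm)",
                  if (is.null(nb)) 0L else nrow(nb), cutoff))
  top$bonds <- rbind(top$bonds, nb)
  top
}

#' Construct a coordinate trajectory
#'
#' @param coords either a 3-d array `[frame, atom, xyz]` or a list of n x 3
#'   matrices, in nm.
#' @param times frame times in ps; defaults to `0, 1, 2, ...`.
#' @return A `Trajectory` object with fields `coords`, `times`, `n_frames`.
#' @export
trajectory <- function(coords, times = NULL) {
  if (is.list(coords)) {
    nf <- length(coords)
    if (!nf) stop("trajectory: need at least one frame")
    na <- nrow(coords[[1]])
    arr <- array(NA_real_, c(nf, na, 3))
    for (i in seq_len(nf)) {
      if (nrow(coords[[i]]) != na)
        stop(sprintf("trajectory: frame %d has %d atoms, expected %d",
                     i, nrow(coords[[i]]), na))
      arr[i, , ] <- coords[[i]]
    }
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  nf <- dim(coords)[1]
  if (nf < 1) stop("trajectory: need at least one frame")
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf)
    stop("trajectory: times length does not match frame count")
  structure(list(coords = coords, times = as.numeric(times), n_frames = nf),
            class = "Trajectory")
}

#' Extract one frame of a trajectory as an n x 3 matrix
#' @param traj a [trajectory()] object.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > traj$n_frames) stop("frame_coords: frame out of range")
  matrix(traj$coords[i, , ], ncol = 3)
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.6g..%.6g ps\n",
              x$n_frames, dim(x$coords)[2], min(x$times), max(x$times)))
  invisible(x)
}
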