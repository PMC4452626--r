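# Conformational model of the beta,alpha(1<->1) diglucosamine linkage.
#
# The builder produces a backbone-only beta-D-GlcN-(1<->1)-alpha-D-GlcN
# disaccharide: two pyranose rings in idealized 4C1 chairs joined
# C1-O1-C1' with user-controlled glycosidic torsions.  Acyl chains and
# phosphates are replaced by single-heavy-atom caps (N2, O3, O4, C6): the
# backbone conformation of these trehalose-type linkages is independent of
# the substituents, so the bare scaffold carries all the inter-proton
# distance information (H1-H1', H5-H2') the NOE comparison needs.
#
# Stereochemical conventions (validated against force-field minimized
# methyl alpha/beta-D-glucopyranoside geometries during development):
#   * 4C1 D-ring torsions alternate +55/-55 deg starting at O5-C1-C2-C3;
#   * alpha anomeric centre: O1 axial, improper torsion(O1,O5,C1,C2) = -120;
#   * beta anomeric centre: O1 equatorial, improper +120;
#   * exo-anomeric (gauche) wells: phi_alpha = +60, phi_beta = -60, with
#     phi_alpha = tors(O5a, C1a, O1, C1b) and phi_beta = tors(C1a, O1, C1b, O5b).

.B_CC <- 0.1526  # nm
.B_CO <- 0.143
.B_CH <- 0.109
.B_CN <- 0.147
.ANG_RING <- 111      # ring internal angle, deg (cyclohexane-like chair)
.ANG_TET <- 109.4712  # tetrahedral
.ANG_COC <- 117       # glycosidic C-O-C
.TOR_RING <- 55       # chair ring torsion magnitude

# place atom D given reference chain A-B-C: |C-D| = bond, angle(B,C,D),
# torsion(A,B,C,D) -- natural extension reference frame
.place <- function(a, b, c, bond, angle, torsion) {
  th <- .rad(angle)
  ph <- .rad(torsion)
  b2 <- c - b
  u2 <- b2 / vec_norm(b2)
  n <- c((b - a)[2] * b2[3] - (b - a)[3] * b2[2],
         (b - a)[3] * b2[1] - (b - a)[1] * b2[3],
         (b - a)[1] * b2[2] - (b - a)[2] * b2[1])
  un <- n / vec_norm(n)
  um <- c(un[2] * u2[3] - un[3] * u2[2],
          un[3] * u2[1] - un[1] * u2[3],
          un[1] * u2[2] - un[2] * u2[1])
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + u2 * d[1] + um * d[2] + un * d[3]
}

# the two tetrahedral directions at centre `p` not occupied by unit
# directions to neighbours u, v; returned as list(axial=, equatorial=)
# decided against the ring normal `nrm`
.remaining_directions <- function(p, u, v, nrm) {
  du <- (u - p) / vec_norm(u - p)
  dv <- (v - p) / vec_norm(v - p)
  s <- du + dv
  e1 <- s / vec_norm(s)
  cr <- c(du[2] * dv[3] - du[3] * dv[2],
          du[3] * dv[1] - du[1] * dv[3],
          du[1] * dv[2] - du[2] * dv[1])
  e2 <- cr / vec_norm(cr)
  cth <- cos(.rad(.ANG_TET))
  aa <- -2 * cth / vec_norm(s)  # component along -e1 so that dot(d, du)=cos
  bb <- sqrt(max(0, 1 - aa^2))
  d1 <- -aa * e1 + bb * e2
  d2 <- -aa * e1 - bb * e2
  if (abs(sum(d1 * nrm)) >= abs(sum(d2 * nrm)))
    list(axial = d1, equatorial = d2)
  else
    list(axial = d2, equatorial = d1)
}

# fourth tetrahedral direction at centre p with three occupied neighbours
.fourth_direction <- function(p, n1, n2, n3) {
  s <- (n1 - p) / vec_norm(n1 - p) + (n2 - p) / vec_norm(n2 - p) +
    (n3 - p) / vec_norm(n3 - p)
  -s / vec_norm(s)
}

.ring_normal <- function(ring) {
  ctr <- colMeans(ring)
  n <- c(0, 0, 0)
  for (i in seq_len(nrow(ring))) {
    u <- ring[i, ] - ctr
    v <- ring[i %% nrow(ring) + 1, ] - ctr
    n <- n + c(u[2] * v[3] - u[3] * v[2],
               u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
  }
  n / vec_norm(n)
}

#' Build an idealized beta,alpha(1<->1) diglucosamine backbone
#'
#' Residue 1 (`AGN`) is the alpha-D-GlcN ring and owns the bridging `O1`;
#' residue 2 (`BGN`) is the beta-D-GlcN ring.  Ring protons `H1`..`H5` are
#' placed on both rings; exocyclic positions carry single-atom caps
#' (`N2`, `O3`, `O4`, `C6`).
#'
#' @param phi_alpha glycosidic torsion O5(alpha)-C1(alpha)-O1-C1(beta), deg.
#' @param phi_beta glycosidic torsion C1(alpha)-O1-C1(beta)-O5(beta), deg.
#' @return A `Structure` (topology + coordinates, nm) with groups
#'   `ring_alpha`, `ring_beta` and full bond list.  A steric clash between
#'   non-bonded heavy atoms closer than 0.15 nm raises a warning but still
#'   returns the structure.
#' @export
build_disaccharide <- function(phi_alpha, phi_beta) {
  stopifnot(phi_alpha > -180, phi_alpha <= 180,
            phi_beta > -180, phi_beta <= 180)
  P <- list()
  # --- alpha ring (residue 1) ---
  P$O5a <- c(0, 0, 0)
  P$C1a <- c(.B_CO, 0, 0)
  P$C2a <- P$C1a + .B_CC * c(-cos(.rad(.ANG_RING)), sin(.rad(.ANG_RING)), 0)
  P$C3a <- .place(P$O5a, P$C1a, P$C2a, .B_CC, .ANG_RING, +.TOR_RING)
  P$C4a <- .place(P$C1a, P$C2a, P$C3a, .B_CC, .ANG_RING, -.TOR_RING)
  P$C5a <- .place(P$C2a, P$C3a, P$C4a, .B_CC, .ANG_RING, +.TOR_RING)
  ring_a <- rbind(P$O5a, P$C1a, P$C2a, P$C3a, P$C4a, P$C5a)
  nrm_a <- .ring_normal(ring_a)
  # anomeric centre: O1 axial (alpha-D), H1 equatorial
  slots <- .remaining_directions(P$C1a, P$O5a, P$C2a, nrm_a)
  P$O1 <- P$C1a + .B_CO * slots$axial
  P$H1a <- P$C1a + .B_CH * slots$equatorial
  # C2: N2 equatorial, H2 axial (D-gluco)
  slots <- .remaining_directions(P$C2a, P$C1a, P$C3a, nrm_a)
  P$N2a <- P$C2a + .B_CN * slots$equatorial
  P$H2a <- P$C2a + .B_CH * slots$axial
  slots <- .remaining_directions(P$C3a, P$C2a, P$C4a, nrm_a)
  P$O3a <- P$C3a + .B_CO * slots$equatorial
  P$H3a <- P$C3a + .B_CH * slots$axial
  slots <- .remaining_directions(P$C4a, P$C3a, P$C5a, nrm_a)
  P$O4a <- P$C4a + .B_CO * slots$equatorial
  P$H4a <- P$C4a + .B_CH * slots$axial
  slots <- .remaining_directions(P$C5a, P$C4a, P$O5a, nrm_a)
  P$C6a <- P$C5a + .B_CC * slots$equatorial
  P$H5a <- P$C5a + .B_CH * slots$axial
  # --- bridge and beta ring (residue 2) ---
  P$C1b <- .place(P$O5a, P$C1a, P$O1, .B_CO, .ANG_COC, phi_alpha)
  P$O5b <- .place(P$C1a, P$O1, P$C1b, .B_CO, .ANG_TET, phi_beta)
  P$C2b <- .place(P$O1, P$O5b, P$C1b, .B_CC, .ANG_RING, +120)  # beta-D improper
  P$C3b <- .place(P$O5b, P$C1b, P$C2b, .B_CC, .ANG_RING, +.TOR_RING)
  P$C4b <- .place(P$C1b, P$C2b, P$C3b, .B_CC, .ANG_RING, -.TOR_RING)
  P$C5b <- .place(P$C2b, P$C3b, P$C4b, .B_CC, .ANG_RING, +.TOR_RING)
  ring_b <- rbind(P$O5b, P$C1b, P$C2b, P$C3b, P$C4b, P$C5b)
  nrm_b <- .ring_normal(ring_b)
  P$H1b <- P$C1b + .B_CH * .fourth_direction(P$C1b, P$O5b, P$O1, P$C2b)
  slots <- .remaining_directions(P$C2b, P$C1b, P$C3b, nrm_b)
  P$N2b <- P$C2b + .B_CN * slots$equatorial
  P$H2b <- P$C2b + .B_CH * slots$axial
  slots <- .remaining_directions(P$C3b, P$C2b, P$C4b, nrm_b)
  P$O3b <- P$C3b + .B_CO * slots$equatorial
  P$H3b <- P$C3b + .B_CH * slots$axial
  slots <- .remaining_directions(P$C4b, P$C3b, P$C5b, nrm_b)
  P$O4b <- P$C4b + .B_CO * slots$equatorial
  P$H4b <- P$C4b + .B_CH * slots$axial
  slots <- .remaining_directions(P$C5b, P$C4b, P$O5b, nrm_b)
  P$C6b <- P$C5b + .B_CC * slots$equatorial
  P$H5b <- P$C5b + .B_CH * slots$axial

  spec <- data.frame(
    key = c("O5a", "C1a", "C2a", "C3a", "C4a", "C5a", "O1", "N2a", "O3a",
            "O4a", "C6a", "H1a", "H2a", "H3a", "H4a", "H5a",
            "O5b", "C1b", "C2b", "C3b", "C4b", "C5b", "N2b", "O3b",
            "O4b", "C6b", "H1b", "H2b", "H3b", "H4b", "H5b"),
    name = c("O5", "C1", "C2", "C3", "C4", "C5", "O1", "N2", "O3",
             "O4", "C6", "H1", "H2", "H3", "H4", "H5",
             "O5", "C1", "C2", "C3", "C4", "C5", "N2", "O3",
             "O4", "C6", "H1", "H2", "H3", "H4", "H5"),
    residue_name = c(rep("AGN", 16), rep("BGN", 15)),
    residue_index = c(rep(1L, 16), rep(2L, 15)),
    stringsAsFactors = FALSE)
  coords <- do.call(rbind, P[spec$key])
  rownames(coords) <- NULL
  at <- function(key) match(key, spec$key)
  bond_keys <- list(
    c("O5a", "C1a"), c("C1a", "C2a"), c("C2a", "C3a"), c("C3a", "C4a"),
    c("C4a", "C5a"), c("C5a", "O5a"), c("C1a", "O1"), c("C1a", "H1a"),
    c("C2a", "N2a"), c("C2a", "H2a"), c("C3a", "O3a"), c("C3a", "H3a"),
    c("C4a", "O4a"), c("C4a", "H4a"), c("C5a", "C6a"), c("C5a", "H5a"),
    c("O1", "C1b"),
    c("O5b", "C1b"), c("C1b", "C2b"), c("C2b", "C3b"), c("C3b", "C4b"),
    c("C4b", "C5b"), c("C5b", "O5b"), c("C1b", "H1b"),
    c("C2b", "N2b"), c("C2b", "H2b"), c("C3b", "O3b"), c("C3b", "H3b"),
    c("C4b", "O4b"), c("C4b", "H4b"), c("C5b", "C6b"), c("C5b", "H5b"))
  bonds <- t(vapply(bond_keys, function(b) c(at(b[1]), at(b[2])),
                    integer(2)))
  top <- topology(spec[, c("name", "residue_name", "residue_index")],
                  bonds = bonds,
                  groups = list(ring_alpha = which(spec$residue_index == 1L),
                                ring_beta = which(spec$residue_index == 2L)))
  # steric clash warning on non-bonded heavy pairs
  heavy <- which(top$atoms$element != "H")
  bonded <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  for (ii in seq_along(heavy)) {
    for (jj in seq_len(ii - 1L)) {
      i <- heavy[ii]; j <- heavy[jj]
      if (paste(min(i, j), max(i, j)) %in% bonded) next
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) < 0.15) {
        warning(sprintf("build_disaccharide: steric clash %s:%s - %s:%s at phi=(%.0f, %.0f)",
                        top$atoms$residue_name[i], top$atoms$name[i],
                        top$atoms$residue_name[j], top$atoms$name[j],
                        phi_alpha, phi_beta))
      }
    }
  }
  structure(list(topology = top, coordinates = coords), class = "Structure")
}

#' Measure the glycosidic torsions of a (1<->1) linkage
#'
#' `phi_alpha = tors(O5, C1, O1, C1')` with the alpha ring first (the residue
#' owning the bridging `O1`), `phi_beta = tors(C1, O1, C1', O5')`.
#'
#' @param coords n x 3 coordinates (nm).
#' @param top a [topology()] with residues named as in [build_disaccharide()]
#'   (alpha ring = residue containing atom `O1`).
#' @return A `GlycosidicTorsions`: list with `phi_alpha`, `phi_beta` in deg.
#' @export
measure_glycosidic_torsions <- function(coords, top) {
  a <- top$atoms
  o1 <- which(a$name == "O1")
  if (length(o1) != 1) stop("measure_glycosidic_torsions: need exactly one bridging O1")
  res_a <- a$residue_index[o1]
  res_b <- setdiff(unique(a$residue_index), res_a)
  if (length(res_b) != 1) stop("measure_glycosidic_torsions: need exactly two residues")
  pick <- function(res, nm) {
    i <- which(a$residue_index == res & a$name == nm)
    if (length(i) != 1)
      stop("measure_glycosidic_torsions: missing atom ", nm,
           " in residue ", res)
    coords[i, ]
  }
  phi_a <- dihedral(pick(res_a, "O5"), pick(res_a, "C1"), coords[o1, ],
                    pick(res_b, "C1"))
  phi_b <- dihedral(pick(res_a, "C1"), coords[o1, ], pick(res_b, "C1"),
                    pick(res_b, "O5"))
  structure(list(phi_alpha = phi_a, phi_beta = phi_b),
            class = "GlycosidicTorsions")
}

#' @export
print.GlycosidicTorsions <- function(x, ...) {
  cat(sprintf("phi_alpha = %.2f deg, phi_beta = %.2f deg\n",
              x$phi_alpha, x$phi_beta))
  invisible(x)
}

#' Classify a torsion pair against the double exo-anomeric well
#'
#' `syn-exo/syn-exo` iff `phi_alpha` is within 40 deg of +60 and `phi_beta`
#' within 40 deg of -60 (strict edges); otherwise `other`.
#'
#' @param t a `GlycosidicTorsions` (or list with `phi_alpha`, `phi_beta`).
#' @return `"syn-exo/syn-exo"` or `"other"`.
#' @export
classify_conformation <- function(t) {
  da <- abs(wrap_angle(t$phi_alpha - 60))
  db <- abs(wrap_angle(t$phi_beta + 60))
  if (da < 40 && db < 40) "syn-exo/syn-exo" else "other"
}

#' Six ring torsions of one pyranose ring
#'
#' Torsions along O5-C1-C2-C3-C4-C5 cyclically; a 4C1 chair shows alternating
#' signs with magnitudes near 55 deg.
#'
#' @param coords n x 3 coordinates.
#' @param top topology from [build_disaccharide()].
#' @param ring `"alpha"` or `"beta"`.
#' @export
ring_torsions <- function(coords, top, ring = c("alpha", "beta")) {
  ring <- match.arg(ring)
  res <- if (ring == "alpha") 1L else 2L
  a <- top$atoms
  order <- c("O5", "C1", "C2", "C3", "C4", "C5")
  idx <- vapply(order, function(nm)
    which(a$residue_index == res & a$name == nm), integer(1))
  vapply(seq_len(6), function(i) {
    q <- idx[c(i, i %% 6 + 1, (i + 1) %% 6 + 1, (i + 2) %% 6 + 1)]
    dihedral(coords[q[1], ], coords[q[2], ], coords[q[3], ], coords[q[4], ])
  }, numeric(1))
}

#' Sample a conformer ensemble about a torsion centre
#'
#' Draws `n` torsion pairs independently from Gaussians centred on the given
#' well (wrapped to (-180, 180]) and builds one conformer per pair.  The
#' default spread of 15 deg mimics thermal libration within a torsion well.
#'
#' @param center length-2 numeric `(phi_alpha, phi_beta)` in deg.
#' @param spread_deg Gaussian standard deviation in deg.
#' @param n number of conformers.
#' @param seed RNG seed (recorded in the result).
#' @return A `ConformerEnsemble`: list with `trajectory` (frames =
#'   conformers), `topology`, `torsions` (n x 2), `center`, `spread_deg`,
#'   `seed`.
#' @export
sample_ensemble <- function(center = c(60, -60), spread_deg = 15, n = 1000L,
                            seed = 1L) {
  stopifnot(n >= 1, spread_deg >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  phis <- cbind(wrap_angle(stats::rnorm(n, center[1], spread_deg)),
                wrap_angle(stats::rnorm(n, center[2], spread_deg)))
  frames <- vector("list", n)
  top <- NULL
  for (i in seq_len(n)) {
    s <- build_disaccharide(phis[i, 1], phis[i, 2])
    if (is.null(top)) top <- s$topology
    frames[[i]] <- s$coordinates
  }
  structure(list(trajectory = trajectory(frames), topology = top,
                 torsions = phis, center = center, spread_deg = spread_deg,
                 seed = seed),
            class = "ConformerEnsemble")
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  cat(sprintf("ConformerEnsemble: %d conformers about (%.0f, %.0f) deg, spread %.0f deg, seed %d\n",
              nrow(x$torsions), x$center[1], x$center[2], x$spread_deg,
              x$seed))
  invisible(x)
}
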