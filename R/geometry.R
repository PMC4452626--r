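# Vector geometry: distances, angles, dihedrals, Kabsch superposition, RMSD.
# All lengths in nm; all public angles in degrees.

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

vec_norm <- function(v) sqrt(sum(v * v))

#' Angle at vertex `b` of the triple a-b-c
#'
#' @param a,b,c numeric length-3 coordinates in nm.
#' @return Angle in degrees in \[0, 180\].
#' @export
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu == 0 || nv == 0) stop("angle_deg: coincident points give a degenerate angle")
  ct <- sum(u * v) / (nu * nv)
  .deg(acos(max(-1, min(1, ct))))
}

#' Dihedral (torsion) angle of four points
#'
#' Signed torsion p1-p2-p3-p4 following the IUPAC convention: looking from p2
#' towards p3, a clockwise rotation of the far bond relative to the near bond
#' is positive.  The value lies in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates in nm.
#' @return Torsion in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- vec_norm(b2)
  if (nb2 == 0 || vec_norm(n1) < 1e-12 || vec_norm(n2) < 1e-12)
    stop("dihedral: degenerate geometry (coincident or collinear points)")
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * b2) / nb2
  ang <- .deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# wrap any angle in degrees to (-180, 180]
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a <= -180] <- a[a <= -180] + 360
  if (any(a == -180)) a[a == -180] <- 180
  a
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD between
#' `mobile[fit_selection, ]` and `reference[fit_selection, ]`, then evaluates
#' the RMSD of `measure_selection` under that same transform (no refit).
#' Reflections are excluded: molecular chirality is preserved by flipping the
#' sign of the smallest singular vector when needed.
#'
#' @param mobile,reference n x 3 coordinate matrices (nm) sharing atom order.
#' @param fit_selection integer indices (1-based) used for the fit; at least 3
#'   non-collinear atoms.
#' @param measure_selection integer indices on which the reported
#'   `measure_rmsd` is computed; defaults to the fit selection.
#' @return A `SuperpositionResult`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `fit_rmsd`, `measure_rmsd` (nm).
#' @export
kabsch_superpose <- function(mobile, reference,
                             fit_selection = seq_len(nrow(mobile)),
                             measure_selection = fit_selection) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  if (length(fit_selection) < 3)
    stop("kabsch_superpose: need at least 3 fit atoms")
  A <- mobile[fit_selection, , drop = FALSE]
  B <- reference[fit_selection, , drop = FALSE]
  ca <- colMeans(A)
  cb <- colMeans(B)
  A0 <- sweep(A, 2, ca)
  B0 <- sweep(B, 2, cb)
  # collinearity check: rank of centred fit coordinates must be >= 2
  sv <- svd(A0)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30))
    stop("kabsch_superpose: fit selection is collinear")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  translation <- cb - as.vector(R %*% ca)
  transform <- function(X) sweep(X %*% t(R), 2, translation, `+`)
  fitted <- transform(A)
  fit_rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  M <- transform(mobile[measure_selection, , drop = FALSE])
  Mref <- reference[measure_selection, , drop = FALSE]
  measure_rmsd <- sqrt(mean(rowSums((M - Mref)^2)))
  structure(list(rotation = R, translation = translation,
                 fit_rmsd = fit_rmsd, measure_rmsd = measure_rmsd),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: fit_rmsd = %.6f nm, measure_rmsd = %.6f nm\n",
              x$fit_rmsd, x$measure_rmsd))
  invisible(x)
}

#' Per-frame RMSD after rotational fit
#'
#' For every frame of a trajectory, superposes the frame onto a reference
#' structure on `fit_selection` (e.g. the C-alpha backbone) and reports the
#' RMSD of `measure_selection` (e.g. the heavy atoms of a marker residue such
#' as the Phe126 loop of MD-2).  The final-frame value is the quantity usually
#' quoted for end-of-simulation conformational drift.
#'
#' @param trajectory a [trajectory()] object.
#' @param reference n x 3 reference coordinates (nm).
#' @param fit_selection,measure_selection 1-based atom indices.
#' @return List with `rmsd` (nm per frame), `time_ps`, `final` and `mean`.
#' @export
rmsd_timeseries <- function(trajectory, reference, fit_selection,
                            measure_selection = fit_selection) {
  nf <- trajectory$n_frames
  out <- vapply(seq_len(nf), function(i) {
    kabsch_superpose(frame_coords(trajectory, i), reference,
                     fit_selection, measure_selection)$measure_rmsd
  }, numeric(1))
  list(rmsd = out, time_ps = trajectory$times,
       final = out[nf], mean = mean(out))
}
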