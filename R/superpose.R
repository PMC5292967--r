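#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle` degrees about the (normalized) `axis`.
#'
#' @param axis length-3 direction vector (normalized internally)
#' @param angle_deg rotation angle in degrees
#' @return a 3 x 3 proper orthogonal matrix
#' @export
rotation_matrix <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero-length rotation axis")
  a <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis and angle of a rotation matrix
#'
#' The angle equals `acos((trace(R) - 1) / 2)` in `[0, 180]` degrees but
#' is evaluated as `atan2(|skew(R)| / 2, (trace(R) - 1) / 2)`, which
#' stays accurate near 0 and 180 where the arc cosine loses half the
#' significant digits. The axis sign is chosen to make the angle
#' positive; near 0 or 180 degrees the axis is geometrically degenerate
#' and flagged as such.
#'
#' @param R 3 x 3 proper rotation matrix
#' @return list with `axis` (unit 3-vector), `angle` (degrees) and
#'   `degenerate` (logical)
#' @export
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nv <- sqrt(sum(v^2))
  ang <- atan2(nv / 2, (tr - 1) / 2) * 180 / pi
  degen <- FALSE
  if (nv > 1e-8) {
    axis <- v / nv
  } else if (ang < 90) {          # angle ~ 0: any axis works
    axis <- c(0, 0, 1); degen <- TRUE
  } else {                        # angle ~ 180: axis from R + I
    M <- R + diag(3)
    j <- which.max(colSums(M^2))
    axis <- M[, j] / sqrt(sum(M[, j]^2))
    degen <- TRUE
  }
  list(axis = axis, angle = ang, degenerate = degen)
}

new_rigid_transform <- function(R, t, rmsd_after = NA_real_) {
  aa <- rotation_axis_angle(R)
  structure(list(rotation = R, translation = as.numeric(t),
                 axis = aa$axis, angle = aa$angle,
                 axis_degenerate = aa$degenerate,
                 rmsd_after = rmsd_after),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  cat(sprintf("  angle: %.4f deg about axis (%.4f, %.4f, %.4f)%s\n",
              x$angle, x$axis[1], x$axis[2], x$axis[3],
              if (isTRUE(x$axis_degenerate)) "  [axis degenerate]" else ""))
  cat(sprintf("  translation: (%.3f, %.3f, %.3f) A\n",
              x$translation[1], x$translation[2], x$translation[3]))
  if (is.finite(x$rmsd_after))
    cat(sprintf("  rmsd after fit: %.4f A\n", x$rmsd_after))
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param x an n x 3 coordinate matrix or a [pdb_structure()]
#' @param transform a `rigid_transform` (or a list with `rotation`,
#'   `translation`)
#' @param selection optional [atom_select()] restricting which atoms move
#'   (structures only)
#' @return object of the same kind as `x`, transformed
#' @export
apply_transform <- function(x, transform, selection = NULL) {
  R <- transform$rotation; t <- transform$translation
  if (inherits(x, "pdb_structure")) {
    xyz <- coords(x, selection)
    return(set_coords(x, sweep(xyz %*% t(R), 2, -t), selection))
  }
  sweep(as.matrix(x) %*% t(R), 2, -t)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of
#' `mobile` onto `reference` over paired coordinates. Reflections are
#' excluded by sign-correcting the smallest singular direction, so
#' chirality is preserved.
#'
#' @param mobile,reference paired n x 3 coordinate matrices, n >= 3,
#'   non-collinear
#' @return a `rigid_transform` carrying `mobile` onto `reference`, with
#'   `rmsd_after` the post-fit RMSD
#' @export
superpose <- function(mobile, reference) {
  m <- as.matrix(mobile); r <- as.matrix(reference)
  if (nrow(m) != nrow(r)) stop("coordinate sets differ in length")
  if (nrow(m) < 3) stop("need at least 3 paired atoms for a rigid fit")
  cm <- colMeans(m); cr <- colMeans(r)
  mc <- sweep(m, 2, cm); rc <- sweep(r, 2, cr)
  sv <- svd(crossprod(mc, rc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30))
    stop("degenerate geometry: paired coordinates are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cr - as.numeric(R %*% cm)
  fitted <- sweep(m %*% t(R), 2, -t)
  new_rigid_transform(R, t, rmsd_val(fitted, r))
}

rmsd_val <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Root-mean-square deviation between paired coordinates
#'
#' @param a,b paired n x 3 coordinate matrices
#' @param fit if TRUE, RMSD after optimal rigid superposition; if FALSE
#'   (default) the raw coordinate RMSD
#' @return RMSD in angstrom
#' @export
rmsd <- function(a, b, fit = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in length")
  if (nrow(a) == 0) stop("empty coordinate sets")
  if (fit) superpose(a, b)$rmsd_after else rmsd_val(a, b)
}

#' Rigid-body rotation of one monomer between two conformations
#'
#' First superposes `complex_b` onto `complex_a` over `frame_selection`
#' (the shared reference frame, typically the transducer transmembrane
#' core), then computes the residual rigid transform carrying the
#' `monomer_selection` atoms of `a` onto those of `b`. The residual
#' transform's angle is the monomer's rigid-body rotation between the two
#' quaternary arrangements.
#'
#' @param complex_a,complex_b [pdb_structure()] objects
#' @param monomer_selection [atom_select()] picking the moving monomer
#' @param frame_selection [atom_select()] picking the common frame
#' @param chain_map optional chain mapping passed to
#'   [pair_common_atoms()]
#' @return a `rigid_transform` (see [superpose()])
#' @export
relative_monomer_rotation <- function(complex_a, complex_b,
                                      monomer_selection, frame_selection,
                                      chain_map = NULL) {
  fr <- pair_common_atoms(complex_a, complex_b, frame_selection, chain_map)
  tf_frame <- superpose(fr$xyz_b, fr$xyz_a)
  b_aligned <- apply_transform(complex_b, tf_frame)
  mo <- pair_common_atoms(complex_a, b_aligned, monomer_selection, chain_map)
  superpose(mo$xyz_a, mo$xyz_b)
}
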