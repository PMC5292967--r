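#' Displacement field of a conformational transition
#'
#' Superposes `v` onto `u` over `frame_selection` (all paired Calpha by
#' default, so any overall rigid-body difference is removed first), then
#' returns the per-atom displacement of the atoms picked by `selection`
#' and the corresponding RMSD.
#'
#' @param u,v [pdb_structure()] objects (start and end conformations)
#' @param selection [atom_select()] for the analysed atoms (default all
#'   Calpha)
#' @param frame_selection [atom_select()] for the superposition frame
#'   (default: same as `selection`)
#' @param chain_map optional chain mapping passed to
#'   [pair_common_atoms()]
#' @return list with `displacement` (3n-vector, angstrom, atom-major
#'   x,y,z order), `rmsd_initial`, `atoms` (paired identity table) and
#'   `xyz_u` (the paired start coordinates)
#' @export
transition_vector <- function(u, v, selection = atom_select(name = "CA"),
                              frame_selection = selection, chain_map = NULL) {
  fr <- pair_common_atoms(u, v, frame_selection, chain_map)
  tf <- superpose(fr$xyz_b, fr$xyz_a)
  v_aligned <- apply_transform(v, tf)
  pr <- pair_common_atoms(u, v_aligned, selection, chain_map)
  disp <- pr$xyz_b - pr$xyz_a
  list(displacement = as.numeric(t(disp)),
       rmsd_initial = sqrt(mean(rowSums(disp^2))),
       atoms = pr$atoms, xyz_u = pr$xyz_a)
}

.nonzero_mode_idx <- function(modes) {
  which(seq_along(modes$frequencies) > modes$n_zero_modes)
}

#' Overlap of a displacement with each normal mode
#'
#' Per-mode overlap is the absolute cosine between the displacement and
#' the (orthonormal) mode vector; the cumulative overlap over the k
#' lowest nonzero modes is the root-sum-square of the per-mode values.
#' Zero-frequency modes are excluded: they carry no internal deformation.
#'
#' @param displacement 3n displacement vector (from
#'   [transition_vector()])
#' @param modes a `mode_set` over the same nodes
#' @return list with `per_mode` (|cosine| per nonzero mode, ascending
#'   frequency), `cumulative` (non-decreasing, <= 1) and `mode_index`
#'   (positions of the nonzero modes inside the mode set)
#' @export
mode_overlap <- function(displacement, modes) {
  d <- as.numeric(displacement)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop("zero displacement: overlap undefined")
  if (length(d) != nrow(modes$vectors))
    stop("displacement length does not match the mode set")
  idx <- .nonzero_mode_idx(modes)
  ov <- abs(as.numeric(crossprod(modes$vectors[, idx, drop = FALSE], d))) / nd
  list(per_mode = ov, cumulative = sqrt(cumsum(ov^2)), mode_index = idx)
}

#' Least-squares fit of a transition by the k lowest nonzero modes
#'
#' With orthonormal modes the least-squares amplitudes are plain
#' projections; the residual RMSD obeys the Pythagorean decomposition
#' `rmsd_initial^2 = explained^2 + residual^2`.
#'
#' @inheritParams mode_overlap
#' @param k number of lowest nonzero modes to use (`k = 0` is allowed
#'   and leaves the whole displacement unexplained)
#' @return list with `coefficients` (amplitudes, angstrom), `fitted`
#'   (3n-vector), `rmsd_residual`, `rmsd_explained` and `mode_index`
#' @export
best_k_fit <- function(displacement, modes, k) {
  d <- as.numeric(displacement)
  idx <- .nonzero_mode_idx(modes)
  if (k > length(idx))
    stop("k = ", k, " exceeds the ", length(idx), " available nonzero modes")
  n_atoms <- length(d) / 3
  use <- idx[seq_len(k)]
  if (k == 0) {
    fitted <- numeric(length(d)); coef <- numeric(0)
  } else {
    V <- modes$vectors[, use, drop = FALSE]
    coef <- as.numeric(crossprod(V, d))
    fitted <- as.numeric(V %*% coef)
  }
  res <- d - fitted
  list(coefficients = coef, fitted = fitted,
       rmsd_residual = sqrt(sum(res^2) / n_atoms),
       rmsd_explained = sqrt(sum(fitted^2) / n_atoms),
       mode_index = use)
}

#' Classify a mode's character over rigid groups
#'
#' Restricts the mode to each rigid group and fits the restriction by an
#' infinitesimal rigid motion `t + omega x (r - c)` about the group
#' centroid (linear least squares). About the centroid the constant
#' translation field and the rotation field are orthogonal, so the
#' squared norm splits exactly into translation, rotation and internal
#' (residual deformation) fractions summing to one. The translation's
#' projection on the membrane normal is the piston component.
#'
#' @param mode 3n mode vector (one column of a `mode_set`)
#' @param nodes n x 3 node coordinates the mode is defined over
#' @param groups named list of node-index vectors (the rigid groups)
#' @param frame a [membrane_frame()] for the piston projection
#' @return data frame, one row per group: `translation_fraction`,
#'   `rotation_fraction`, `internal_fraction`, `piston` (angstrom per
#'   unit mode amplitude) and `norm_fraction` (share of the mode's norm
#'   carried by the group)
#' @export
classify_mode <- function(mode, nodes, groups, frame = membrane_frame()) {
  v <- as.numeric(mode)
  nodes <- as.matrix(nodes)
  if (length(v) != 3 * nrow(nodes)) stop("mode length does not match nodes")
  total2 <- sum(v^2)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < 3) stop("group '", g, "' has fewer than 3 nodes")
    rows <- as.numeric(t(outer((idx - 1) * 3, 1:3, "+")))
    vg <- v[rows]
    xg <- nodes[idx, , drop = FALSE]
    ctr <- colMeans(xg)
    rel <- sweep(xg, 2, ctr)
    nb <- length(idx)
    A <- matrix(0, 3 * nb, 6)
    for (a in 1:3) A[seq(a, 3 * nb, by = 3), a] <- 1
    for (i in seq_len(nb)) {
      r <- rel[i, ]
      # rows of the cross-product map omega -> omega x r
      A[3 * i - 2, 4:6] <- c(0, r[3], -r[2])
      A[3 * i - 1, 4:6] <- c(-r[3], 0, r[1])
      A[3 * i,     4:6] <- c(r[2], -r[1], 0)
    }
    fit <- stats::lm.fit(A, vg)
    t_part <- A[, 1:3] %*% fit$coefficients[1:3]
    r_part <- A[, 4:6] %*% fit$coefficients[4:6]
    g2 <- sum(vg^2)
    data.frame(group = g,
               translation_fraction = sum(t_part^2) / g2,
               rotation_fraction = sum(r_part^2) / g2,
               internal_fraction = sum(fit$residuals^2) / g2,
               piston = sum(fit$coefficients[1:3] * frame$normal),
               norm_fraction = g2 / total2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Displace a structure along a mode combination
#'
#' Adds `amplitude x sum(coefficients_i x mode_i)` to the selected
#' atoms, the standard way of generating mode-following models and
#' animation frames.
#'
#' @param u a [pdb_structure()]
#' @param modes a `mode_set` whose nodes are `selection` of `u`, in atom
#'   order
#' @param coefficients amplitudes per mode (matched to `mode_index`, or
#'   to the k lowest nonzero modes when `mode_index` is NULL)
#' @param amplitude overall scale factor (default 1)
#' @param selection [atom_select()] naming the mode nodes in `u`
#' @param mode_index which modes the coefficients refer to (default: the
#'   `length(coefficients)` lowest nonzero modes)
#' @return the displaced [pdb_structure()]
#' @export
displace_along_modes <- function(u, modes, coefficients, amplitude = 1,
                                 selection = atom_select(name = "CA"),
                                 mode_index = NULL) {
  if (is.null(mode_index))
    mode_index <- .nonzero_mode_idx(modes)[seq_along(coefficients)]
  if (length(mode_index) != length(coefficients))
    stop("coefficients and mode_index differ in length")
  xyz <- coords(u, selection)
  if (nrow(modes$vectors) != 3 * nrow(xyz))
    stop("mode set does not match the selected atoms")
  if (length(coefficients)) {
    dv <- amplitude * as.numeric(
      modes$vectors[, mode_index, drop = FALSE] %*% coefficients)
    xyz <- xyz + matrix(dv, ncol = 3, byrow = TRUE)
  }
  set_coords(u, xyz, selection)
}

#' Full transition report
#'
#' Bundles [transition_vector()], [mode_overlap()], [best_k_fit()] and
#' [classify_mode()] into one record for a U-to-V style analysis.
#'
#' @inheritParams transition_vector
#' @param modes a `mode_set` computed on `u` over `selection`
#' @param k number of lowest nonzero modes for the best-k fit
#' @param groups optional named list of node-index vectors for
#'   mode-character classification of the first three nonzero modes
#' @param frame [membrane_frame()] used for piston components
#' @return an object of class `transition_report`
#' @export
transition_report <- function(u, v, modes, k = 10,
                              selection = atom_select(name = "CA"),
                              frame_selection = selection,
                              groups = NULL, frame = membrane_frame()) {
  tv <- transition_vector(u, v, selection, frame_selection)
  ov <- mode_overlap(tv$displacement, modes)
  fit <- best_k_fit(tv$displacement, modes, k)
  characters <- NULL
  if (!is.null(groups)) {
    idx <- .nonzero_mode_idx(modes)
    take <- idx[seq_len(min(3, length(idx)))]
    characters <- do.call(rbind, lapply(seq_along(take), function(m) {
      cbind(mode = m,
            classify_mode(modes$vectors[, take[m]], tv$xyz_u, groups, frame))
    }))
  }
  structure(list(rmsd_initial = tv$rmsd_initial,
                 per_mode_overlap = ov$per_mode,
                 cumulative_overlap = ov$cumulative,
                 best_k = k,
                 best_k_coefficients = fit$coefficients,
                 rmsd_residual = fit$rmsd_residual,
                 rmsd_explained = fit$rmsd_explained,
                 mode_character = characters,
                 displacement = tv$displacement,
                 atoms = tv$atoms),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat("transition_report\n")
  cat(sprintf("  rmsd initial:  %.3f A\n", x$rmsd_initial))
  cat(sprintf("  best-%d fit:    residual %.3f A (explained %.3f A)\n",
              x$best_k, x$rmsd_residual, x$rmsd_explained))
  nshow <- min(10, length(x$per_mode_overlap))
  cat("  per-mode overlap:",
      paste(sprintf("%.3f", x$per_mode_overlap[seq_len(nshow)]), collapse = " "),
      "\n")
  cat(sprintf("  cumulative overlap over %d modes: %.3f\n",
              nshow, x$cumulative_overlap[nshow]))
  invisible(x)
}
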