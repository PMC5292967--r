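#' Run the full U-to-V analysis workflow
#'
#' Orchestrates the whole pipeline on either a synthetic planted complex
#' or a pair of PDB files: atom pairing and frame superposition, monomer
#' rigid-body rotation, designated-helix (G) axis angle, piston and
#' axial rotation of the designated transducer helix, elastic-network
#' normal modes of the start conformation (full or RTB), transition
#' overlaps and the best-k mode fit, a V-like displaced model, and
#' optionally the lattice clash summaries of the two packing presets.
#'
#' @param config list of settings; unset entries take defaults:
#'   \describe{
#'     \item{u, v}{paths to PDB files, or NULL to simulate}
#'     \item{rotation_deg, piston_A, axial_deg, noise_A, seed}{synthetic
#'       plant parameters (defaults 8.5, 0.5, 19, 0, 1)}
#'     \item{target_rmsd_A}{rescale the planted transition to this exact
#'       RMSD before analysis (NULL: keep as planted)}
#'     \item{cutoff_A, k, blocks}{ENM cutoff (10), number of modes for
#'       the best-k fit (10), block scheme `"per-helix"` /
#'       `"per-residue"`}
#'     \item{frame_chains, frame_resno}{superposition frame selection
#'       (defaults: the unperturbed transducer TM1 helices)}
#'     \item{monomer_chain}{moving monomer for the rigid-body angle
#'       ("A")}
#'     \item{lattice}{logical: also run the open/tight lattice clash
#'       comparison (default TRUE for synthetic runs)}
#'     \item{out_dir}{if set, write `report.json`, the V-like model and
#'       a mode-trajectory PDB there}
#'   }
#' @return nested report list (class `u2v_report`); every number in it
#'   is produced by the package's exported operations
#' @export
run_u2v_analysis <- function(config = list()) {
  cfg <- utils::modifyList(list(
    u = NULL, v = NULL,
    rotation_deg = 8.5, piston_A = 0.5, axial_deg = 19,
    noise_A = 0, seed = 1L, target_rmsd_A = NULL,
    cutoff_A = 10, k = 10L, blocks = "per-helix",
    frame_chains = c("B", "D"), frame_resno = 1:100,
    monomer_chain = "A", lattice = NULL, out_dir = NULL), config)

  synthetic <- is.null(cfg$u)
  if (synthetic) {
    spec <- complex_spec(receptor_rotation = cfg$rotation_deg,
                         piston = cfg$piston_A,
                         tm2_axial_rotation = cfg$axial_deg,
                         noise_sigma = cfg$noise_A, seed = cfg$seed)
    uv <- make_u_v_pair(spec)
    u <- uv$u; v <- uv$v; gt <- uv$ground_truth
    if (is.null(cfg$lattice)) cfg$lattice <- TRUE
  } else {
    u <- read_pdb(cfg$u); v <- read_pdb(cfg$v); gt <- NULL
    if (is.null(cfg$lattice)) cfg$lattice <- FALSE
  }
  ca <- atom_select(name = "CA")
  frame_sel <- atom_select(chain = cfg$frame_chains, resno = cfg$frame_resno,
                           name = "CA")
  mono_sel <- atom_select(chain = cfg$monomer_chain, name = "CA")
  frame <- if (synthetic) gt$frame else estimate_membrane_frame(u, frame_sel)

  # --- rigid-body geometry -------------------------------------------
  tf_mono <- relative_monomer_rotation(u, v, mono_sel, frame_sel)
  g_chain <- if (synthetic) gt$g_helix$chain else cfg$monomer_chain
  g_resno <- if (synthetic) gt$g_helix$resno else cfg$frame_resno
  fr_pair <- pair_common_atoms(u, v, frame_sel)
  v_al <- apply_transform(v, superpose(fr_pair$xyz_b, fr_pair$xyz_a))
  ax_u <- fit_helix_axis(u, g_chain, g_resno)
  ax_v <- fit_helix_axis(v_al, g_chain, g_resno)
  geometry <- list(
    monomer_rotation_deg = tf_mono$angle,
    monomer_rotation_axis = tf_mono$axis,
    g_helix_angle_deg = interhelix_angle(ax_u, ax_v))
  if (synthetic) {
    geometry$piston_A <- piston_displacement(
      u, v_al, gt$tm2$chain, gt$tm2$resno, frame)
    geometry$tm2_axial_rotation_deg <- helix_axial_rotation(
      u, v_al, gt$tm2$chain, gt$tm2$resno)
  }

  # --- normal modes on U ---------------------------------------------
  # geometry above describes the conformers as given; the transition
  # analysis optionally standardizes the overall amplitude so
  # mode-fit residuals are comparable across runs
  v_tr <- if (is.null(cfg$target_rmsd_A)) v else
    scale_transition(u, v, cfg$target_rmsd_A, selection = ca,
                     frame_selection = frame_sel)
  model <- enm(u, ca, cutoff = cfg$cutoff_A)
  blocks <- switch(cfg$blocks,
                   "per-helix" = blocks_by_chain(u, ca),
                   "per-residue" = seq_len(nrow(model$nodes)),
                   cfg$blocks)
  modes <- rtb_modes(model, blocks)
  groups <- NULL
  if (synthetic) {
    at <- u$atoms[selection_mask(u, ca), ]
    groups <- lapply(gt$groups, function(chs) which(at$chain %in% chs))
  }
  rep_tr <- transition_report(u, v_tr, modes, k = cfg$k, selection = ca,
                              frame_selection = frame_sel,
                              groups = groups, frame = frame)

  # --- V-like model from the fitted mode combination -----------------
  fit <- best_k_fit(rep_tr$displacement, modes, cfg$k)
  vlike <- displace_along_modes(u, modes, fit$coefficients,
                                selection = ca, mode_index = fit$mode_index)
  fr_tr <- pair_common_atoms(u, v_tr, frame_sel)
  v_tr_al <- apply_transform(v_tr, superpose(fr_tr$xyz_b, fr_tr$xyz_a))
  pr_vv <- pair_common_atoms(vlike, v_tr_al, ca)
  vlike_rmsd <- rmsd(pr_vv$xyz_a, pr_vv$xyz_b)

  report <- list(
    config = cfg[setdiff(names(cfg), c("u", "v"))],
    input = if (synthetic) "synthetic" else c(u = cfg$u, v = cfg$v),
    ground_truth = if (synthetic)
      gt[c("receptor_rotation", "piston", "tm2_axial_rotation",
           "noise_sigma", "seed")],
    geometry = geometry,
    enm = list(n_nodes = nrow(model$nodes), cutoff_A = cfg$cutoff_A,
               n_components = model$n_components,
               n_zero_modes = modes$n_zero_modes,
               provenance = modes$provenance),
    transition = list(
      rmsd_initial_A = rep_tr$rmsd_initial,
      rmsd_residual_A = rep_tr$rmsd_residual,
      rmsd_explained_A = rep_tr$rmsd_explained,
      k = cfg$k,
      per_mode_overlap = rep_tr$per_mode_overlap[seq_len(min(
        cfg$k, length(rep_tr$per_mode_overlap)))],
      cumulative_overlap_k = rep_tr$cumulative_overlap[min(
        cfg$k, length(rep_tr$cumulative_overlap))],
      vlike_model_rmsd_A = vlike_rmsd),
    mode_character = rep_tr$mode_character)

  if (isTRUE(cfg$lattice)) {
    probe <- atom_select(chain = "H")
    open <- lattice_clash_report(make_lattice_fixture("open"), probe)
    tight <- lattice_clash_report(make_lattice_fixture("tight"), probe)
    report$lattice <- list(
      open = list(clashing = open$clashing, counts = as.list(open$counts)),
      tight = list(clashing = tight$clashing, counts = as.list(tight$counts)))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_pdb(vlike, file.path(cfg$out_dir, "vlike.pdb"))
    write_mode_trajectory(u, modes, .nonzero_mode_idx(modes)[1],
                          file.path(cfg$out_dir, "mode1_traj.pdb"))
  }
  structure(report, class = c("u2v_report", "list"))
}

#' @export
print.u2v_report <- function(x, ...) {
  cat("U-to-V analysis report\n")
  g <- x$geometry
  cat(sprintf("  monomer rotation: %.3f deg | G-helix angle: %.3f deg\n",
              g$monomer_rotation_deg, g$g_helix_angle_deg))
  if (!is.null(g$piston_A))
    cat(sprintf("  TM2 piston: %+.3f A | TM2 axial rotation: %.3f deg\n",
                g$piston_A, g$tm2_axial_rotation_deg))
  tr <- x$transition
  cat(sprintf("  transition RMSD %.3f A -> residual %.3f A after best-%d-mode fit\n",
              tr$rmsd_initial_A, tr$rmsd_residual_A, tr$k))
  cat(sprintf("  V-like model vs V: %.3f A RMSD\n", tr$vlike_model_rmsd_A))
  if (!is.null(x$lattice))
    cat(sprintf("  lattice: open %s, tight %s\n",
                if (x$lattice$open$clashing) "clashing" else "clean",
                if (x$lattice$tight$clashing) "clashing" else "clean"))
  invisible(x)
}

#' Write a one-mode animation as a multi-MODEL PDB trajectory
#'
#' Displaces the structure along a single mode with a sinusoidal
#' amplitude sweep, one MODEL record per frame.
#'
#' @param u a [pdb_structure()]
#' @param modes a `mode_set` over `selection` of `u`
#' @param mode_index which mode to animate (index into the mode set)
#' @param path output PDB path
#' @param amplitude peak amplitude in angstrom of the largest-moving atom
#' @param n_frames frames per period
#' @param selection node selection
#' @return invisibly, the path
#' @export
write_mode_trajectory <- function(u, modes, mode_index, path,
                                  amplitude = 3, n_frames = 11,
                                  selection = atom_select(name = "CA")) {
  vec <- modes$vectors[, mode_index]
  per_atom <- sqrt(rowSums(matrix(vec, ncol = 3, byrow = TRUE)^2))
  scale <- amplitude / max(per_atom)
  phases <- sin(seq(0, 2 * pi, length.out = n_frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(phases)) {
    s <- displace_along_modes(u, modes, coefficients = scale * phases[f],
                              selection = selection, mode_index = mode_index)
    tmp <- tempfile(fileext = ".pdb")
    write_pdb(s, tmp)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- readLines(tmp)
    writeLines(lines[lines != "END"], con)
    writeLines("ENDMDL", con)
    unlink(tmp)
  }
  writeLines("END", con)
  invisible(path)
}
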