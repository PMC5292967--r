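#' Specification of an ideal alpha-helix
#'
#' Standard helical parametrization: 1.5 angstrom rise and 100 degrees
#' twist per residue (3.6 residues per turn) on a 2.3 angstrom radius,
#' the textbook Calpha geometry of an alpha-helix.
#'
#' @param n_residues number of residues (>= 4)
#' @param rise rise per residue along the axis, angstrom
#' @param twist twist per residue, degrees
#' @param radius Calpha radius about the axis, angstrom
#' @param axis_origin first-residue axis point, angstrom
#' @param axis_direction unit axis direction (checked to 1e-8)
#' @param chain chain ID given to the helix
#' @param start_res residue number of the first residue
#' @param phase azimuthal phase of the first residue, degrees
#' @return a `helix_spec`
#' @export
helix_spec <- function(n_residues, rise = 1.5, twist = 100, radius = 2.3,
                       axis_origin = c(0, 0, 0),
                       axis_direction = c(0, 0, 1),
                       chain = "A", start_res = 1L, phase = 0) {
  if (n_residues < 4) stop("a helix needs at least 4 residues")
  nrm <- sqrt(sum(axis_direction^2))
  if (abs(nrm - 1) > 1e-8)
    stop("axis_direction must be unit length (|norm - 1| <= 1e-8)")
  structure(list(n_residues = as.integer(n_residues), rise = rise,
                 twist = twist, radius = radius,
                 axis_origin = as.numeric(axis_origin),
                 axis_direction = axis_direction / nrm,
                 chain = chain, start_res = as.integer(start_res),
                 phase = phase),
            class = "helix_spec")
}

#' Build a Calpha helix from its specification
#'
#' Deterministic: the same spec always yields identical coordinates.
#' Residues are alanines with unit occupancy.
#'
#' @param spec a [helix_spec()]
#' @return a [pdb_structure()] with one CA atom per residue
#' @export
make_helix <- function(spec) {
  d <- spec$axis_direction
  u <- orthogonal_vector(d)
  w <- crossprod_vec(d, u)
  i <- seq_len(spec$n_residues) - 1
  th <- (spec$phase + i * spec$twist) * pi / 180
  xyz <- outer(i * spec$rise, d) +
    spec$radius * (outer(cos(th), u) + outer(sin(th), w))
  xyz <- sweep(xyz, 2, -spec$axis_origin)
  atoms <- data.frame(
    serial = seq_len(spec$n_residues),
    name = "CA", resid = "ALA", chain = spec$chain,
    resno = spec$start_res + as.integer(i), ins = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 0, element = "C", type = "ATOM",
    stringsAsFactors = FALSE)
  pdb_structure(atoms, label = sprintf("helix %s", spec$chain))
}

.merge_structures <- function(structs, cell = NULL, space_group = NULL,
                              label = "") {
  atoms <- do.call(rbind, lapply(structs, function(s) s$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  pdb_structure(atoms, cell, space_group, label)
}

#' Specification of a synthetic two-protomer receptor-transducer complex
#'
#' The complex emulates the architecture of a 2:2 membrane
#' photoreceptor-transducer module: a four-helix transmembrane
#' transducer core on the pseudo-C2 axis (the membrane normal, +z
#' pointing intracellular), flanked by two three-helix receptors. The
#' second protomer is the exact C2 image of the first before any
#' asymmetric perturbation is planted.
#'
#' Planted ground truth, all recoverable downstream:
#' \itemize{
#'   \item `receptor_rotation`: rigid-body tilt of each receptor about
#'     an in-membrane axis through a pivot at its intracellular end
#'     (the receptor-transducer contact), so the inter-receptor crevice
#'     widens toward the cytoplasmic side in the V-form. Default
#'     8.5 degrees, the magnitude reported for the U-to-V transition of
#'     the sensory rhodopsin II / HtrII complex.
#'   \item `piston`: translation of the designated transducer helix
#'     (TM2 of protomer 1) along the membrane normal; default 0.5
#'     angstrom toward the cytoplasm.
#'   \item `tm2_axial_rotation`: rotation of that same helix about its
#'     own axis; default 19 degrees.
#' }
#' Isotropic Gaussian noise of width `noise_sigma` is added to every
#' coordinate of both conformations after planting.
#'
#' @param receptor_rotation degrees, >= 0
#' @param piston angstrom, along +z (intracellular)
#' @param tm2_axial_rotation degrees about the TM2 helix axis
#' @param noise_sigma angstrom, >= 0
#' @param seed integer RNG seed for the noise
#' @param n_res_tm,n_res_receptor residues per transducer / receptor
#'   helix
#' @return a `complex_spec`
#' @export
complex_spec <- function(receptor_rotation = 8.5, piston = 0.5,
                         tm2_axial_rotation = 19,
                         noise_sigma = 0, seed = 1L,
                         n_res_tm = 26L, n_res_receptor = 22L) {
  if (receptor_rotation < 0) stop("receptor_rotation must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(receptor_rotation = receptor_rotation, piston = piston,
                 tm2_axial_rotation = tm2_axial_rotation,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 n_res_tm = as.integer(n_res_tm),
                 n_res_receptor = as.integer(n_res_receptor),
                 c2_axis = c(0, 0, 1)),
            class = "complex_spec")
}

# Helix layout of protomer 1; protomer 2 is its C2 image about z.
# Chains: A = receptor 1 (three segments), B = transducer 1 (TM1, TM2),
#         C = receptor 2, D = transducer 2.
.protomer_layout <- function(spec) {
  ztm <- -(spec$n_res_tm - 1) * 1.5 / 2     # centre TM helices on z = 0
  zrec <- -(spec$n_res_receptor - 1) * 1.5 / 2
  list(
    tm1 = helix_spec(spec$n_res_tm, axis_origin = c(4, -4, ztm),
                     chain = "B", start_res = 1L, phase = 0),
    tm2 = helix_spec(spec$n_res_tm, axis_origin = c(4, 4, ztm),
                     chain = "B", start_res = 101L, phase = 40),
    rec1 = helix_spec(spec$n_res_receptor, axis_origin = c(14, -4, zrec),
                      chain = "A", start_res = 1L, phase = 80),
    rec2 = helix_spec(spec$n_res_receptor, axis_origin = c(14, 4, zrec),
                      chain = "A", start_res = 101L, phase = 160),
    recG = helix_spec(spec$n_res_receptor, axis_origin = c(19, 0, zrec),
                      chain = "A", start_res = 201L, phase = 240))
}

.c2_image <- function(s, chain_map) {
  R <- rotation_matrix(c(0, 0, 1), 180)
  s <- apply_transform(s, list(rotation = R, translation = c(0, 0, 0)))
  s$atoms$chain <- unname(chain_map[s$atoms$chain])
  s
}

#' Generate a planted U/V conformer pair
#'
#' U is the symmetric ("closed") complex; V applies the planted receptor
#' rigid-body rotation to both receptors (each about the C2 image of the
#' other's axis, so V remains C2-symmetric in the receptors), then the
#' piston translation and axial rotation to the designated transducer
#' helix. Noise, when requested, is drawn independently for U and V with
#' the spec's seed, after all planting.
#'
#' @param spec a [complex_spec()]
#' @return list with `u`, `v` ([pdb_structure()] objects) and
#'   `ground_truth`: the exact planted transform per rigid group, the
#'   designated helix ranges and the rigid-group chain sets
#' @export
make_u_v_pair <- function(spec) {
  lay <- .protomer_layout(spec)
  p1 <- lapply(lay, make_helix)
  cmap <- c(A = "C", B = "D")
  p2 <- lapply(p1, .c2_image, chain_map = cmap)
  u <- .merge_structures(c(p1, p2), label = "U (symmetric)")

  # receptor rotation: in-membrane axis (y) through a pivot at the
  # receptor's intracellular end (the receptor-transducer contact);
  # the extracellular ends swing toward the core, so the inter-receptor
  # crevice widens on the cytoplasmic side (V opens toward the
  # cytoplasm)
  zrec <- (spec$n_res_receptor - 1) * 1.5 / 2
  pivot1 <- c(14, 0, zrec)
  axis1 <- c(0, 1, 0)
  R1 <- rotation_matrix(axis1, spec$receptor_rotation)
  tf1 <- list(rotation = R1, translation = pivot1 - as.numeric(R1 %*% pivot1))
  C2 <- rotation_matrix(c(0, 0, 1), 180)
  pivot2 <- as.numeric(C2 %*% pivot1)
  axis2 <- as.numeric(C2 %*% axis1)
  R2 <- C2 %*% R1 %*% t(C2)
  tf2 <- list(rotation = R2, translation = pivot2 - as.numeric(R2 %*% pivot2))

  v <- u
  v <- apply_transform(v, tf1, atom_select(chain = "A"))
  v <- apply_transform(v, tf2, atom_select(chain = "C"))

  # designated transducer helix: TM2 of protomer 1 (chain B, 101-126)
  tm2_sel <- atom_select(chain = "B", resno = 101:(100 + spec$n_res_tm))
  if (spec$tm2_axial_rotation != 0) {
    ax <- lay$tm2$axis_direction
    org <- lay$tm2$axis_origin
    Ra <- rotation_matrix(ax, spec$tm2_axial_rotation)
    tfa <- list(rotation = Ra, translation = org - as.numeric(Ra %*% org))
    v <- apply_transform(v, tfa, tm2_sel)
  }
  if (spec$piston != 0) {
    v <- apply_transform(v, list(rotation = diag(3),
                                 translation = spec$piston * spec$c2_axis),
                         tm2_sel)
  }
  v$label <- "V (planted)"

  if (spec$noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    u <- .jitter(u, spec$noise_sigma)
    v <- .jitter(v, spec$noise_sigma)
  }
  gt <- list(
    receptor_rotation = spec$receptor_rotation,
    receptor_transforms = list(A = tf1, C = tf2),
    rotation_axes = list(A = axis1, C = axis2),
    pivots = list(A = pivot1, C = pivot2),
    piston = spec$piston,
    tm2_axial_rotation = spec$tm2_axial_rotation,
    g_helix = list(chain = "A", resno = 201:(200 + spec$n_res_receptor)),
    tm2 = list(chain = "B", resno = 101:(100 + spec$n_res_tm)),
    groups = list(receptor_A = "A", receptor_B = "C",
                  transducer = c("B", "D")),
    frame = membrane_frame(spec$c2_axis, c(0, 0, 0)),
    noise_sigma = spec$noise_sigma, seed = spec$seed)
  list(u = u, v = v, ground_truth = gt)
}

.jitter <- function(s, sigma) {
  xyz <- coords(s)
  set_coords(s, xyz + matrix(stats::rnorm(length(xyz), sd = sigma), ncol = 3))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

#' Rescale a planted transition to an exact RMSD
#'
#' Replaces `v` by `u + s (v - u)` over the paired atoms (after frame
#' superposition), with `s` chosen so that the transition RMSD equals
#' `target_rmsd` exactly. Used to plant a transition of a prescribed
#' overall amplitude while preserving its direction.
#'
#' @param u,v [pdb_structure()] objects with identical atom sets
#' @param target_rmsd desired transition RMSD, angstrom
#' @param selection,frame_selection as in [transition_vector()]
#' @return the rescaled `v` structure
#' @export
scale_transition <- function(u, v, target_rmsd,
                             selection = atom_select(name = "CA"),
                             frame_selection = selection) {
  tv <- transition_vector(u, v, selection, frame_selection)
  if (tv$rmsd_initial < 1e-12) stop("u and v are identical; nothing to scale")
  s <- target_rmsd / tv$rmsd_initial
  disp <- matrix(tv$displacement, ncol = 3, byrow = TRUE)
  out <- u
  xyz_new <- tv$xyz_u + s * disp
  # write back through the paired-atom identities
  at <- out$atoms
  key <- paste(at$chain, at$resno, at$ins, at$name, sep = "|")
  pk <- paste(tv$atoms$chain, tv$atoms$resno, tv$atoms$ins, tv$atoms$name,
              sep = "|")
  idx <- match(pk, key)
  at$x[idx] <- xyz_new[, 1]; at$y[idx] <- xyz_new[, 2]; at$z[idx] <- xyz_new[, 3]
  out$atoms <- at
  out$label <- sprintf("V (rescaled to %.3f A)", target_rmsd)
  out
}

#' Generate a crystal-lattice fixture with an appended protruding domain
#'
#' Builds the synthetic complex with a two-helix appended domain (chain
#' H, emulating a HAMP-like protrusion past the membrane region) and
#' wraps it in a unit cell. Two named placements are shipped:
#' \describe{
#'   \item{`"open"`}{P1 cell of 200 angstrom: the molecule is isolated
#'     and no symmetry mate comes anywhere near the probe.}
#'   \item{`"tight"`}{P2(1)2(1)2 cell whose c edge is shorter than the
#'     molecule's height, so the appended domain of one layer
#'     interpenetrates the transducer of the next layer along the
#'     stacking direction — at least one steric clash by construction.}
#' }
#'
#' @param preset `"open"` or `"tight"`
#' @param spec a [complex_spec()] for the underlying complex
#' @return a [pdb_structure()] with cell + space group; the appended
#'   domain is chain `"H"`
#' @export
make_lattice_fixture <- function(preset = c("open", "tight"),
                                 spec = complex_spec(receptor_rotation = 0,
                                                     piston = 0,
                                                     tm2_axial_rotation = 0)) {
  preset <- match.arg(preset)
  uv <- make_u_v_pair(spec)
  base <- uv$u
  # appended domain: continue straight up from TM2 of protomer 1
  ztop <- (spec$n_res_tm - 1) * 1.5 / 2
  hamp <- make_helix(helix_spec(18L, axis_origin = c(4, 4, ztop + 2),
                                chain = "H", start_res = 1L, phase = 40))
  full <- .merge_structures(list(base, hamp), label = paste0("lattice-", preset))
  if (preset == "open") {
    full$cell <- c(200, 200, 200, 90, 90, 90)
    full$space_group <- "P 1"
  } else {
    # c shorter than the molecular height, offset by half the 1.5 A
    # Calpha grid: the next layer's TM2 runs through the appended
    # domain on the same axis, atoms interleaved at ~2 A spacing
    ztm <- -(spec$n_res_tm - 1) * 1.5 / 2
    c_edge <- (ztop + 2) - ztm + 0.75
    full$cell <- c(150, 150, c_edge, 90, 90, 90)
    full$space_group <- "P 21 21 2"
    # place the molecule off the rotation axes of the in-plane operators
    # so their images stay remote and only the stacking contact remains
    xyz <- coords(full)
    xyz[, 1] <- xyz[, 1] + 40; xyz[, 2] <- xyz[, 2] + 55
    xyz[, 3] <- xyz[, 3] - min(xyz[, 3])
    full <- set_coords(full, xyz)
  }
  full
}
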