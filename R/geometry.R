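#' Fit a helix axis
#'
#' The dominant principal direction of the mean-centred Calpha
#' coordinates gives the initial axis estimate; it is then refined by
#' the second-difference construction (see below), which removes the
#' partial-turn bias the principal direction carries on short helices
#' and is exact for an ideal helix. The direction is sign-oriented from
#' the N- toward the C-terminus. `fit_rms` is the root-mean-square
#' distance of the Calpha atoms from the fitted axis line; for an ideal
#' helix this equals the helix radius.
#'
#' @param structure a [pdb_structure()]
#' @param chain chain ID of the helix
#' @param resno residue-number range of the helix (integer vector)
#' @return a `helix_axis`: list with `origin` (centroid), `direction`
#'   (unit vector, N to C), `residue_range`, `fit_rms`
#' @export
fit_helix_axis <- function(structure, chain, resno) {
  sel <- atom_select(chain = chain, resno = resno, name = "CA")
  xyz <- coords(structure, sel)
  if (nrow(xyz) < 5) stop("need at least 5 Calpha atoms to fit a helix axis")
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  sv <- svd(xc)
  if (sv$d[1]^2 < 2 * sv$d[2]^2)
    stop("ill-defined helix axis: no dominant principal direction")
  dir <- .helix_direction_sd(xyz, sv$v[, 1])
  # orient N -> C
  if (sum(dir * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) dir <- -dir
  perp <- xc - outer(as.numeric(xc %*% dir), dir)
  structure(list(origin = ctr, direction = dir,
                 residue_range = list(chain = chain, resno = range(resno)),
                 fit_rms = sqrt(mean(rowSums(perp^2)))),
            class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("helix_axis chain %s %d-%d: direction (%.3f, %.3f, %.3f), fit_rms %.2f A\n",
              x$residue_range$chain, x$residue_range$resno[1],
              x$residue_range$resno[2],
              x$direction[1], x$direction[2], x$direction[3], x$fit_rms))
  invisible(x)
}

#' Angle between two helix axes
#'
#' @param axis_a,axis_b `helix_axis` objects (or unit 3-vectors)
#' @param directed if TRUE (default) the axes keep their N-to-C polarity
#'   and antiparallel helices read as 180 degrees; if FALSE the angle is
#'   folded into `[0, 90]`
#' @return angle in degrees
#' @export
interhelix_angle <- function(axis_a, axis_b, directed = TRUE) {
  da <- if (inherits(axis_a, "helix_axis")) axis_a$direction else axis_a / sqrt(sum(axis_a^2))
  db <- if (inherits(axis_b, "helix_axis")) axis_b$direction else axis_b / sqrt(sum(axis_b^2))
  d <- sum(da * db)
  if (!directed) d <- abs(d)
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Membrane reference frame
#'
#' A unit membrane normal, a centre point, and a sign convention:
#' `+normal` points toward the intracellular (IC) side.
#'
#' @param normal membrane normal (normalized internally)
#' @param center a point in the membrane mid-plane
#' @return a `membrane_frame`
#' @export
membrane_frame <- function(normal = c(0, 0, 1), center = c(0, 0, 0)) {
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("zero membrane normal")
  structure(list(normal = normal / n, center = as.numeric(center)),
            class = "membrane_frame")
}

#' Estimate a membrane frame from transmembrane helices
#'
#' Takes the dominant principal direction of the pooled Calpha
#' coordinates of a transmembrane selection as the membrane normal — the
#' usual proxy when no explicit bilayer is present.
#'
#' @param structure a [pdb_structure()]
#' @param tm_selection [atom_select()] covering the TM helices
#' @return a [membrane_frame()]
#' @export
estimate_membrane_frame <- function(structure,
                                    tm_selection = atom_select(name = "CA")) {
  xyz <- coords(structure, tm_selection)
  if (nrow(xyz) < 5) stop("too few atoms to estimate a membrane frame")
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  membrane_frame(sv$v[, 1], ctr)
}

.helix_end_residues <- function(structure, chain, resno, frame,
                                end = c("cytoplasmic", "extracellular", "whole"),
                                fraction = 0.25) {
  end <- match.arg(end)
  sel <- atom_select(chain = chain, resno = resno, name = "CA")
  at <- structure$atoms[selection_mask(structure, sel), , drop = FALSE]
  if (!nrow(at)) stop("empty helix range")
  res <- sort(unique(at$resno))
  if (end == "whole") return(res)
  # which end of the residue ladder points intracellular (+normal)?
  proj <- vapply(res, function(r) {
    i <- at$resno == r
    sum(colMeans(cbind(at$x[i], at$y[i], at$z[i])) * frame$normal)
  }, numeric(1))
  k <- max(1L, ceiling(length(res) * fraction))
  lo <- res[seq_len(k)]; hi <- res[seq.int(length(res) - k + 1L, length(res))]
  hi_is_ic <- mean(proj[res %in% hi]) >= mean(proj[res %in% lo])
  if ((end == "cytoplasmic") == hi_is_ic) hi else lo
}

#' Piston displacement of a helix segment along the membrane normal
#'
#' Signed projection onto the membrane normal of the displacement of the
#' Calpha centroid of the chosen helix end between two (pre-superposed)
#' conformations. The cytoplasmic end defaults to the terminal quarter of
#' the residue ladder on the intracellular side. Structures must already
#' share a frame: superpose them over a common selection first.
#'
#' @param a,b [pdb_structure()] objects in a common frame
#' @param chain,resno helix chain and residue range
#' @param frame a [membrane_frame()]
#' @param end `"cytoplasmic"` (default), `"extracellular"` or `"whole"`
#' @param fraction fraction of residues counted as the helix end
#' @return signed displacement in angstrom (positive toward IC)
#' @export
piston_displacement <- function(a, b, chain, resno, frame,
                                end = "cytoplasmic", fraction = 0.25) {
  res <- .helix_end_residues(a, chain, resno, frame, end, fraction)
  sel <- atom_select(chain = chain, resno = res, name = "CA")
  pr <- pair_common_atoms(a, b, sel)
  sum((colMeans(pr$xyz_b) - colMeans(pr$xyz_a)) * frame$normal)
}

# Helix direction from second differences of the Calpha trace: the
# second difference of an ideal helix lies in the plane normal to the
# axis, so successive cross products give the axis exactly, with no
# partial-turn bias (unlike the PCA direction). Falls back to PCA when
# the trace is too short.
.helix_direction_sd <- function(xyz, fallback) {
  if (nrow(xyz) < 5) return(fallback)
  w <- diff(diff(xyz))
  cr <- t(vapply(seq_len(nrow(w) - 1),
                 function(i) crossprod_vec(w[i, ], w[i + 1, ]), numeric(3)))
  nrm <- sqrt(rowSums(cr^2))
  ok <- nrm > 1e-10
  if (!any(ok)) return(fallback)
  cr <- cr[ok, , drop = FALSE] / nrm[ok]
  cr <- cr * sign(as.numeric(cr %*% fallback))  # consistent polarity
  d <- colMeans(cr)
  d / sqrt(sum(d^2))
}

#' Rotation of a helix about its own axis
#'
#' Measures how far a helix has spun about its own axis between two
#' conformations, independently of any piston translation along it.
#' The second copy is first aligned so the two fitted axes coincide
#' (minimal rotation mapping axis b onto axis a, centroids matched);
#' each residue's Calpha is then projected onto the plane normal to the
#' common axis and the circular mean of the per-residue angular
#' displacements is returned. Right-handed about the N-to-C axis
#' direction.
#'
#' @param a,b [pdb_structure()] objects containing the helix
#' @param chain,resno helix chain and residue-number range
#' @return mean axial rotation in degrees, in (-180, 180]
#' @export
helix_axial_rotation <- function(a, b, chain, resno) {
  ax_a <- fit_helix_axis(a, chain, resno)
  ax_b <- fit_helix_axis(b, chain, resno)
  sel <- atom_select(chain = chain, resno = resno, name = "CA")
  pr <- pair_common_atoms(a, b, sel)
  dir_a <- .helix_direction_sd(pr$xyz_a, ax_a$direction)
  dir_b <- .helix_direction_sd(pr$xyz_b, ax_b$direction)
  # align b's axis onto a's by the minimal rotation between directions
  v <- crossprod_vec(dir_b, dir_a)
  s <- sqrt(sum(v^2)); cth <- sum(dir_a * dir_b)
  R <- if (s < 1e-12) {
    if (cth > 0) diag(3) else rotation_matrix(orthogonal_vector(dir_a), 180)
  } else rotation_matrix(v, atan2(s, cth) * 180 / pi)
  xb <- sweep(pr$xyz_b, 2, ax_b$origin) %*% t(R)
  xa <- sweep(pr$xyz_a, 2, ax_a$origin)
  d <- dir_a
  u <- orthogonal_vector(d); w <- crossprod_vec(d, u)
  ang <- function(m) atan2(m %*% w, m %*% u)
  dth <- ang(xb) - ang(xa)
  atan2(mean(sin(dth)), mean(cos(dth))) * 180 / pi
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

orthogonal_vector <- function(d) {
  u <- crossprod_vec(d, c(1, 0, 0))
  if (sum(u^2) < 1e-12) u <- crossprod_vec(d, c(0, 1, 0))
  u / sqrt(sum(u^2))
}

# Side-chain atom roles for interaction typing (heavy atoms only).
.positive_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                        HIS = c("ND1", "NE2"))
.negative_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.donor_atoms <- list(
  "*" = "N",  # backbone amide of every residue
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  ASN = "ND2", GLN = "NE2", TRP = "NE1", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")
.acceptor_atoms <- list(
  "*" = "O",  # backbone carbonyl
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

.atom_role <- function(resid, name, table) {
  hit <- name %in% table[["*"]]
  spec <- table[resid]
  for (i in seq_along(resid)) {
    t <- spec[[i]]
    if (!is.null(t) && name[i] %in% t) hit[i] <- TRUE
  }
  hit
}

#' Detect inter-atomic contacts between two atom sets
#'
#' Classifies every cross pair within `contact_dist` of each other as one
#' of `clash` (non-bonded heavy atoms closer than `clash_dist`),
#' `salt_bridge` (oppositely charged side-chain terminal atoms within
#' `sb_dist`), `hydrogen_bond` (donor/acceptor heavy atoms within
#' `hb_dist`; with hydrogens absent, the antecedent-donor-acceptor angle
#' must be at least `hb_angle_min` when an antecedent atom is resolved)
#' or plain `contact`. Thresholds are the standard structural-biology
#' values and are all configurable. Pairs within one residue are skipped
#' when both sets come from the same structure.
#'
#' Calpha-only input cannot carry donors or charges, so only
#' `clash`/`contact` kinds are reported (with a warning).
#'
#' @param a,b [pdb_structure()] objects (may be the same object)
#' @param sel_a,sel_b optional [atom_select()] restricting each side
#' @param contact_dist,hb_dist,sb_dist,clash_dist distance thresholds, A
#' @param hb_angle_min minimum antecedent-donor-acceptor angle, degrees
#' @param same_structure treat `a` and `b` as the same molecule and skip
#'   intra-residue pairs (default: TRUE when `a` and `b` are identical)
#' @return data frame of contact records: atom identities, `distance`,
#'   `kind`, `angle` (degrees, NA when not applicable)
#' @export
detect_contacts <- function(a, b, sel_a = NULL, sel_b = NULL,
                            contact_dist = 4.5, hb_dist = 3.5,
                            sb_dist = 4.0, clash_dist = 2.5,
                            hb_angle_min = 90,
                            same_structure = identical(a, b)) {
  at_a <- a$atoms[selection_mask(a, sel_a), , drop = FALSE]
  at_b <- b$atoms[selection_mask(b, sel_b), , drop = FALSE]
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), name_a = character(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), name_b = character(),
                      distance = numeric(), kind = character(),
                      angle = numeric(), stringsAsFactors = FALSE)
  if (!nrow(at_a) || !nrow(at_b)) return(empty)
  ca_only <- all(at_a$name == "CA") && all(at_b$name == "CA")
  if (ca_only)
    warning("Calpha-only input: restricting contact kinds to clash/contact")
  xa <- cbind(at_a$x, at_a$y, at_a$z)
  xb <- cbind(at_b$x, at_b$y, at_b$z)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= contact_dist^2, arr.ind = TRUE)
  if (same_structure && nrow(hit)) {
    same_res <- at_a$chain[hit[, 1]] == at_b$chain[hit[, 2]] &
      at_a$resno[hit[, 1]] == at_b$resno[hit[, 2]] &
      at_a$ins[hit[, 1]] == at_b$ins[hit[, 2]]
    hit <- hit[!same_res, , drop = FALSE]
  }
  if (!nrow(hit)) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  dist <- sqrt(d2[hit])
  kind <- rep("contact", length(i))
  angle <- rep(NA_real_, length(i))
  kind[dist < clash_dist] <- "clash"
  if (!ca_only) {
    pos_a <- .atom_role2(at_a, .positive_atoms)[i]
    neg_a <- .atom_role2(at_a, .negative_atoms)[i]
    pos_b <- .atom_role2(at_b, .positive_atoms)[j]
    neg_b <- .atom_role2(at_b, .negative_atoms)[j]
    sb <- kind == "contact" & dist <= sb_dist &
      ((pos_a & neg_b) | (neg_a & pos_b))
    kind[sb] <- "salt_bridge"
    don_a <- .atom_role(at_a$resid, at_a$name, .donor_atoms)[i]
    acc_a <- .atom_role(at_a$resid, at_a$name, .acceptor_atoms)[i]
    don_b <- .atom_role(at_b$resid, at_b$name, .donor_atoms)[j]
    acc_b <- .atom_role(at_b$resid, at_b$name, .acceptor_atoms)[j]
    cand <- which(kind == "contact" & dist <= hb_dist &
                    ((don_a & acc_b) | (acc_a & don_b)))
    for (k in cand) {
      if (don_a[k] && acc_b[k]) {
        ang <- .donor_angle(at_a, i[k], xb[j[k], ])
      } else {
        ang <- .donor_angle(at_b, j[k], xa[i[k], ])
      }
      if (is.na(ang) || ang >= hb_angle_min) {
        kind[k] <- "hydrogen_bond"; angle[k] <- ang
      }
    }
  }
  data.frame(chain_a = at_a$chain[i], resno_a = at_a$resno[i],
             resid_a = at_a$resid[i], name_a = at_a$name[i],
             chain_b = at_b$chain[j], resno_b = at_b$resno[j],
             resid_b = at_b$resid[j], name_b = at_b$name[j],
             distance = dist, kind = kind, angle = angle,
             stringsAsFactors = FALSE)
}

.atom_role2 <- function(at, table) .atom_role(at$resid, at$name, table)

# Antecedent-donor-acceptor angle: the antecedent is the nearest heavy
# atom of the same residue covalently plausible (< 1.8 A); NA when none.
.donor_angle <- function(at, idx, acceptor_xyz) {
  same <- which(at$chain == at$chain[idx] & at$resno == at$resno[idx] &
                  at$ins == at$ins[idx])
  same <- setdiff(same, idx)
  if (!length(same)) return(NA_real_)
  dxyz <- c(at$x[idx], at$y[idx], at$z[idx])
  cand <- cbind(at$x[same], at$y[same], at$z[same])
  dd <- sqrt(rowSums(sweep(cand, 2, dxyz)^2))
  ok <- which(dd < 1.8)
  if (!length(ok)) return(NA_real_)
  ante <- cand[ok[which.min(dd[ok])], ]
  v1 <- ante - dxyz; v2 <- acceptor_xyz - dxyz
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}
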