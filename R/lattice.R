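# Built-in general positions for the space groups handled natively.
# Triplets follow International Tables; anything else comes in through
# an operator file of one x,y,z triplet per line.
.space_group_table <- list(
  "P 1" = c("x,y,z"),
  "P 21 21 2" = c("x,y,z", "-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z"),
  "I 21 21 21" = c("x,y,z", "-x,-y+1/2,z", "x,-y,-z+1/2", "-x,y+1/2,-z+1/2",
                   "x+1/2,y+1/2,z+1/2", "-x+1/2,-y,z+1/2",
                   "x+1/2,-y+1/2,-z", "-x+1/2,y,-z"),
  "P 64" = c("x,y,z", "x-y,x,z+2/3", "-y,x-y,z+1/3", "-x,-y,z",
             "-x+y,-x,z+2/3", "y,-x+y,z+1/3"))

.normalize_sg <- function(symbol) {
  s <- toupper(gsub("[ _]", "", symbol))
  hit <- match(s, toupper(gsub("[ _]", "", names(.space_group_table))))
  if (is.na(hit)) NA_character_ else names(.space_group_table)[hit]
}

#' Parse an "x,y,z"-style symmetry-operator triplet
#'
#' @param triplet e.g. `"-x+1/2,y+1/2,-z"` or `"x-y,x,z+2/3"`
#' @return a `symmetry_operator`: list with `R` (3 x 3 matrix acting on
#'   fractional coordinates) and `t` (fractional translation 3-vector)
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("malformed operator triplet: ", triplet)
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    # tokenize into signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sgn <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        R[r, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        t[r] <- t[r] + sgn * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        t[r] <- t[r] + sgn * as.numeric(body)
      } else stop("cannot parse operator term '", tok, "' in: ", triplet)
    }
  }
  structure(list(R = R, t = t, triplet = triplet), class = "symmetry_operator")
}

#' Symmetry operators of a space group
#'
#' Returns the general-position operators of one of the built-in groups
#' (P1: 1; P2(1)2(1)2: 4; I2(1)2(1)2(1): 8 including the body centring;
#' P6(4): 6), or parses a user-supplied operator file with one
#' x,y,z-style triplet per line (`#` comments allowed) for any other
#' group.
#'
#' @param space_group Hermann-Mauguin symbol (spacing-insensitive)
#' @param operator_file optional path to an operator file, used when the
#'   symbol is not built in
#' @return list of `symmetry_operator` objects; the identity is first
#' @export
operators_for <- function(space_group, operator_file = NULL) {
  key <- .normalize_sg(space_group)
  if (!is.na(key)) {
    ops <- lapply(.space_group_table[[key]], parse_symop)
  } else if (!is.null(operator_file)) {
    lines <- trimws(readLines(operator_file, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("operator file contains no triplets")
    ops <- lapply(lines, parse_symop)
  } else {
    stop("unknown space group '", space_group,
         "' and no operator file supplied")
  }
  is_id <- vapply(ops, function(o) all(o$R == diag(3)) && all(o$t %% 1 == 0),
                  logical(1))
  if (sum(is_id) != 1) stop("operator set must contain the identity exactly once")
  c(ops[is_id], ops[!is_id])
}

#' Fractional-to-orthogonal cell matrix
#'
#' Standard PDB convention: `a` along x, `b` in the xy plane.
#'
#' @param cell numeric length-6: a, b, c (angstrom), alpha, beta, gamma
#'   (degrees)
#' @return 3 x 3 matrix `M` with `orthogonal = M %*% fractional`
#' @export
cell_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- (cos(al) - cos(be) * cos(ga)) / sin(ga)
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * v,
           0, 0, cc * sqrt(max(0, sin(be)^2 - v^2))),
         3, 3, byrow = TRUE)
}

#' Expand crystal symmetry mates around a structure
#'
#' Applies every space-group operator combined with integer cell
#' translations and keeps each non-identity image that has at least one
#' atom within `radius` of the base structure. The shift search range is
#' derived from the molecule extent and the cell, so mates are never
#' missed for any sensible radius.
#'
#' @param base a [pdb_structure()] with cell and space group
#' @param radius retain mates with any atom within this distance of the
#'   base (angstrom, default 5)
#' @param operator_file optional operator file for non-built-in groups
#' @return list of mates; each element has `structure` (the transformed
#'   copy), `op` (the operator triplet) and `shift` (integer cell shift)
#' @export
expand_mates <- function(base, radius = 5, operator_file = NULL) {
  if (is.null(base$cell)) stop("structure has no unit cell")
  sg <- if (is.null(base$space_group)) "P 1" else base$space_group
  ops <- operators_for(sg, operator_file)
  M <- cell_matrix(base$cell)
  Minv <- solve(M)
  xyz <- coords(base)
  frac <- t(Minv %*% t(xyz))
  # shift range: enough cells to cover the molecule extent plus radius
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  nshift <- pmin(4L, pmax(1L, ceiling((max(ext) + radius) / base$cell[1:3])))
  shifts <- as.matrix(expand.grid(u = -nshift[1]:nshift[1],
                                  v = -nshift[2]:nshift[2],
                                  w = -nshift[3]:nshift[3]))
  lo <- apply(xyz, 2, min) - radius
  hi <- apply(xyz, 2, max) + radius
  mates <- list()
  for (oi in seq_along(ops)) {
    op <- ops[[oi]]
    f0 <- t(op$R %*% t(frac)) + matrix(op$t, nrow(frac), 3, byrow = TRUE)
    for (si in seq_len(nrow(shifts))) {
      if (oi == 1 && all(shifts[si, ] == 0)) next  # the base itself
      fs <- f0 + matrix(as.numeric(shifts[si, ]), nrow(f0), 3, byrow = TRUE)
      ximg <- t(M %*% t(fs))
      # fast bounding-box rejection before exact distances
      if (any(apply(ximg, 2, max) < lo) || any(apply(ximg, 2, min) > hi)) next
      if (!.within_radius(xyz, ximg, radius)) next
      mate <- set_coords(base, ximg)
      mate$label <- sprintf("%s [%s + (%d,%d,%d)]", base$label, op$triplet,
                            shifts[si, 1], shifts[si, 2], shifts[si, 3])
      mates[[length(mates) + 1]] <- list(structure = mate, op = op$triplet,
                                         shift = as.integer(shifts[si, ]))
    }
  }
  mates
}

.within_radius <- function(a, b, radius) {
  # chunked min-distance check to bound memory on large mates
  r2 <- radius^2
  nb <- nrow(b)
  step <- max(1L, floor(2e6 / nrow(a)))
  for (s in seq(1L, nb, by = step)) {
    idx <- s:min(nb, s + step - 1L)
    d2 <- outer(rowSums(a^2), rowSums(b[idx, , drop = FALSE]^2), "+") -
      2 * a %*% t(b[idx, , drop = FALSE])
    if (any(d2 <= r2)) return(TRUE)
  }
  FALSE
}

#' Inter-mate packing contacts of a probe region
#'
#' Expands symmetry mates and runs [detect_contacts()] between the probe
#' atoms of the base structure and all atoms of every retained mate. The
#' verdict is "clashing" as soon as one clash-kind contact exists — the
#' computational form of the packing argument that discriminates a
#' protruding appended domain that fits the lattice from one that
#' collides with the next crystal layer.
#'
#' @param base a [pdb_structure()] with cell + space group
#' @param probe [atom_select()] picking the probe atoms (e.g. the
#'   appended domain); an empty probe yields an empty, non-clashing
#'   report
#' @param radius mate retention / contact search radius, angstrom
#' @param operator_file optional operator file
#' @param ... thresholds forwarded to [detect_contacts()]
#' @return a `lattice_clash_report`: per-kind counts, per-mate detail,
#'   `clashing` flag
#' @export
lattice_clash_report <- function(base, probe, radius = 5,
                                 operator_file = NULL, ...) {
  kinds <- c("clash", "salt_bridge", "hydrogen_bond", "contact")
  probe_atoms <- sum(selection_mask(base, probe))
  counts <- stats::setNames(integer(4), kinds)
  detail <- list()
  if (probe_atoms > 0) {
    mates <- expand_mates(base, radius, operator_file)
    for (m in mates) {
      ct <- suppressWarnings(
        detect_contacts(base, m$structure, sel_a = probe,
                        contact_dist = min(radius, 4.5),
                        same_structure = FALSE, ...))
      if (nrow(ct)) {
        ct$mate <- m$structure$label
        detail[[length(detail) + 1]] <- ct
        tb <- table(factor(ct$kind, levels = kinds))
        counts <- counts + as.integer(tb)
      }
    }
  }
  contacts <- if (length(detail)) do.call(rbind, detail) else NULL
  structure(list(counts = counts, contacts = contacts,
                 clashing = counts[["clash"]] > 0,
                 n_probe_atoms = probe_atoms, radius = radius),
            class = "lattice_clash_report")
}

#' @export
print.lattice_clash_report <- function(x, ...) {
  cat("lattice_clash_report:",
      if (x$clashing) "CLASHING" else "no clashes", "\n")
  cat(sprintf("  probe atoms: %d, search radius %.1f A\n",
              x$n_probe_atoms, x$radius))
  for (k in names(x$counts))
    cat(sprintf("  %-14s %d\n", k, x$counts[[k]]))
  invisible(x)
}
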