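#' Build an elastic network model from Calpha coordinates
#'
#' Nodes are connected by uniform harmonic springs (spring constant
#' `gamma`) whenever they lie within `cutoff` angstrom of each other —
#' the anisotropic network model. Connectivity of the resulting contact
#' graph is checked and reported: a disconnected model has more than six
#' zero-frequency modes, which usually signals a cutoff that is too
#' short.
#'
#' @param x a [pdb_structure()] or an n x 3 coordinate matrix
#' @param selection [atom_select()] picking the nodes when `x` is a
#'   structure; defaults to all Calpha atoms
#' @param cutoff interaction cutoff in angstrom (default 10)
#' @param gamma uniform spring constant (arbitrary units, default 1)
#' @param masses per-node masses (default 1, i.e. unweighted)
#' @return an object of class `enm`: nodes, cutoff, gamma, masses, the
#'   contact-pair list and the number of connected components
#' @export
enm <- function(x, selection = atom_select(name = "CA"),
                cutoff = 10, gamma = 1, masses = 1) {
  nodes <- if (inherits(x, "pdb_structure")) coords(x, selection) else as.matrix(x)
  n <- nrow(nodes)
  if (n < 2) stop("an elastic network needs at least 2 nodes")
  if (cutoff <= 0) stop("cutoff must be positive")
  masses <- rep_len(masses, n)
  if (any(masses <= 0)) stop("masses must be positive")
  d2 <- as.matrix(stats::dist(nodes))^2
  pairs <- which(upper.tri(d2) & d2 <= cutoff^2 & d2 > 0, arr.ind = TRUE)
  comp <- .graph_components(n, pairs)
  structure(list(nodes = nodes, cutoff = cutoff, gamma = gamma,
                 masses = masses, pairs = pairs,
                 n_components = max(comp), components = comp),
            class = "enm")
}

#' @export
print.enm <- function(x, ...) {
  cat(sprintf("enm: %d nodes, cutoff %.1f A, %d springs, %d connected component%s\n",
              nrow(x$nodes), x$cutoff, nrow(x$pairs), x$n_components,
              if (x$n_components == 1) "" else "s"))
  invisible(x)
}

.graph_components <- function(n, pairs) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  comp
}

#' Assemble the ANM Hessian
#'
#' For each contact pair the 3 x 3 super-element is `-gamma` times the
#' outer product of the unit inter-node vector; diagonal super-elements
#' are minus the sum of the off-diagonal super-elements in their row, so
#' rigid translations are exact zero modes by construction.
#'
#' @param model an [enm()] object
#' @return symmetric positive semi-definite 3n x 3n matrix
#' @export
build_hessian <- function(model) {
  nodes <- model$nodes; n <- nrow(nodes)
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(model$pairs))) {
    i <- model$pairs[k, 1]; j <- model$pairs[k, 2]
    dv <- nodes[j, ] - nodes[i, ]
    dv <- dv / sqrt(sum(dv^2))
    blk <- model$gamma * tcrossprod(dv)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

.mass_weight <- function(model) rep(1 / sqrt(model$masses), each = 3)

.finish_modeset <- function(values, vectors, model, provenance, blocks = NULL) {
  ord <- order(values)
  values <- values[ord]; vectors <- vectors[, ord, drop = FALSE]
  lmax <- max(values, 1e-30)
  values[values < 0 & values > -1e-6 * lmax] <- 0
  # relative threshold, with an absolute floor for the all-rigid case
  # where every eigenvalue is numerical noise
  nzero <- sum(values < max(1e-8 * lmax, 1e-10))
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(vectors))) {
    m <- which.max(abs(vectors[, k]))
    if (vectors[m, k] < 0) vectors[, k] <- -vectors[, k]
  }
  structure(list(frequencies = values, vectors = vectors,
                 n_zero_modes = nzero, provenance = provenance,
                 blocks = blocks, n_nodes = nrow(model$nodes),
                 masses = model$masses),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d modes over %d nodes, %d zero mode%s\n",
              x$provenance, length(x$frequencies), x$n_nodes, x$n_zero_modes,
              if (x$n_zero_modes == 1) "" else "s"))
  nz <- x$frequencies[x$frequencies >= 1e-8 * max(x$frequencies, 1e-30)]
  if (length(nz))
    cat("  lowest nonzero eigenvalues:",
        paste(format(utils::head(nz, 5), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mode_set <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Full normal modes of an elastic network
#'
#' Diagonalizes the (mass-weighted) Hessian and returns the lowest `k`
#' eigenpairs, zero modes included. Zero modes are identified by a
#' relative threshold, eigenvalue < 1e-8 x largest, which is robust to
#' the overall model scale. Returned vectors are orthonormal in the
#' mass-weighted inner product (plain orthonormal for unit masses).
#'
#' @param model an [enm()] object
#' @param k number of lowest modes to keep (default: all 3n)
#' @return a `mode_set`: ascending `frequencies` (eigenvalues),
#'   `vectors` (3n x k Cartesian displacement fields), `n_zero_modes`,
#'   `provenance = "full"`
#' @export
full_modes <- function(model, k = NULL) {
  n3 <- 3 * nrow(model$nodes)
  if (is.null(k)) k <- n3
  if (k > n3) stop("k exceeds the 3n available modes")
  H <- build_hessian(model)
  w <- .mass_weight(model)
  Hw <- H * outer(w, w)
  eg <- eigen(Hw, symmetric = TRUE)
  vals <- rev(eg$values)[seq_len(k)]
  vecs <- eg$vectors[, rev(seq_len(n3))[seq_len(k)], drop = FALSE]
  .finish_modeset(vals, vecs, model, "full")
}

# Orthonormal rigid-body basis of one block (translations + rotations
# about the block centroid); blocks of 1-2 nodes span fewer than 6 DoF
# and the rank-deficient directions are dropped.
.block_basis <- function(xyz) {
  nb <- nrow(xyz)
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  B <- matrix(0, 3 * nb, 6)
  for (a in 1:3) B[seq(a, 3 * nb, by = 3), a] <- 1
  for (a in 1:3) {
    e <- c(0, 0, 0); e[a] <- 1
    rot <- t(apply(rel, 1, function(r) crossprod_vec(e, r)))
    B[, 3 + a] <- as.numeric(t(rot))
  }
  sv <- svd(B)
  keep <- sv$d > 1e-8 * sv$d[1]
  sv$u[, keep, drop = FALSE]
}

#' Rotation-translation-block (RTB) normal modes
#'
#' Projects the Hessian onto the subspace spanned by rigid translations
#' and rotations of each block (six degrees of freedom per block, fewer
#' for one- or two-node blocks), solves the reduced eigenproblem, and
#' maps the eigenvectors back to full 3n-dimensional Cartesian
#' displacement fields. Because the projection matrix has orthonormal
#' columns, the back-projected modes are orthonormal without further
#' work, and every reduced eigenvalue bounds its full-model counterpart
#' from above (variational property).
#'
#' @param model an [enm()] object
#' @param blocks integer vector of length n assigning each node to a
#'   block (e.g. from [blocks_by_chain()]), or a list of node-index
#'   vectors; blocks must partition the nodes
#' @param k number of lowest modes to keep (default: all reduced DoF)
#' @return a `mode_set` with `provenance = "rtb"` and the block map
#' @export
rtb_modes <- function(model, blocks, k = NULL) {
  n <- nrow(model$nodes)
  if (is.list(blocks)) {
    bl <- integer(n)
    for (b in seq_along(blocks)) bl[blocks[[b]]] <- b
    blocks <- bl
  }
  blocks <- as.integer(factor(blocks))
  if (length(blocks) != n || anyNA(blocks))
    stop("blocks must assign every node to a block")
  if (!all(model$masses == model$masses[1]))
    stop("RTB reduction is implemented for uniform masses")
  H <- build_hessian(model)
  ids <- sort(unique(blocks))
  Plist <- lapply(ids, function(b) .block_basis(model$nodes[blocks == b, , drop = FALSE]))
  ncols <- vapply(Plist, ncol, integer(1))
  P <- matrix(0, 3 * n, sum(ncols))
  col0 <- 0L
  for (bi in seq_along(ids)) {
    rows <- as.numeric(t(outer((which(blocks == ids[bi]) - 1) * 3, 1:3, "+")))
    P[rows, col0 + seq_len(ncols[bi])] <- Plist[[bi]]
    col0 <- col0 + ncols[bi]
  }
  Hr <- crossprod(P, H %*% P)
  Hr <- (Hr + t(Hr)) / 2
  eg <- eigen(Hr, symmetric = TRUE)
  m <- ncol(P)
  if (is.null(k)) k <- m
  if (k > m) stop("k exceeds the ", m, " reduced degrees of freedom")
  sel <- rev(seq_len(m))[seq_len(k)]
  vals <- eg$values[sel]
  vecs <- P %*% eg$vectors[, sel, drop = FALSE]
  .finish_modeset(vals, vecs, model, "rtb", blocks = blocks)
}

#' Node-to-block map from chain IDs
#'
#' Assigns every selected node the block of its chain — the "one block
#' per helix" scheme when each helix carries its own chain ID. Runs of
#' residues separated by numbering gaps within one chain are split into
#' separate blocks, so multi-segment chains map to per-segment blocks.
#'
#' @param structure a [pdb_structure()]
#' @param selection node selection, default all Calpha
#' @param split_gaps split blocks at residue-numbering gaps > 1
#' @return integer block id per node
#' @export
blocks_by_chain <- function(structure, selection = atom_select(name = "CA"),
                            split_gaps = TRUE) {
  at <- structure$atoms[selection_mask(structure, selection), , drop = FALSE]
  if (!nrow(at)) stop("empty selection")
  id <- at$chain
  if (split_gaps) {
    gap <- c(FALSE, diff(at$resno) > 1 | at$chain[-1] != at$chain[-nrow(at)])
    id <- paste(at$chain, cumsum(gap), sep = ".")
  }
  as.integer(factor(id, levels = unique(id)))
}
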