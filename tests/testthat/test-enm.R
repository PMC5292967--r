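test_that("the two-node network matches the closed-form spectrum", {
  m <- enm(rbind(c(0, 0, 0), c(5, 0, 0)), cutoff = 10, gamma = 1.5)
  H <- build_hessian(m)
  expect_equal(H, t(H))
  # springs act only along the inter-node direction (x)
  expect_equal(sum(abs(H[, c(2, 3, 5, 6)])), 0)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_close(sort(ev), c(0, 0, 0, 0, 0, 2 * 1.5), 1e-12)
  ms <- full_modes(m)
  expect_equal(ms$n_zero_modes, 5)
  expect_close(max(ms$frequencies), 3, 1e-12)
})

test_that("nodes beyond the cutoff are unconnected", {
  m <- enm(rbind(c(0, 0, 0), c(15, 0, 0)), cutoff = 10)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$n_components, 2)
  expect_equal(sum(abs(build_hessian(m))), 0)
  # two disconnected bodies carry 12 zero modes
  xyz <- rbind(coords(make_helix(helix_spec(8))),
               coords(make_helix(helix_spec(8))) + 40)
  m2 <- enm(xyz, cutoff = 10)
  expect_equal(m2$n_components, 2)
  expect_equal(full_modes(m2)$n_zero_modes, 12)
})

test_that("the Hessian satisfies the super-element row-sum condition", {
  uv <- make_u_v_pair(complex_spec())
  m <- enm(uv$u)
  H <- build_hessian(m)
  n <- nrow(m$nodes)
  for (i in c(1, 17, n)) {
    ii <- (3 * i - 2):(3 * i)
    off <- matrix(0, 3, 3)
    for (j in setdiff(seq_len(n), i)) off <- off + H[ii, (3 * j - 2):(3 * j)]
    expect_close(H[ii, ii], -off, 1e-10)
  }
  # eigenvalues non-negative, exactly 6 zero modes for a connected model
  ms <- full_modes(m, 30)
  expect_equal(m$n_components, 1)
  expect_equal(ms$n_zero_modes, 6)
  expect_true(all(ms$frequencies > -1e-8 * max(ms$frequencies)))
})

test_that("RTB with one node per block reproduces the full spectrum", {
  xyz <- coords(make_helix(helix_spec(12)))
  m <- enm(xyz)
  fm <- full_modes(m)
  rm_ <- rtb_modes(m, seq_len(nrow(xyz)))
  expect_close(rm_$frequencies, fm$frequencies, 1e-6)
  # identical eigenspaces: cross-projection has unit diagonal cosines
  nz <- which(fm$frequencies > 1e-8 * max(fm$frequencies))
  for (k in utils::head(nz, 5))
    expect_close(abs(sum(fm$vectors[, k] * rm_$vectors[, k])), 1, 1e-6)
})

test_that("a single all-structure block leaves only rigid-body modes", {
  xyz <- coords(make_helix(helix_spec(10)))
  m <- enm(xyz)
  rm_ <- rtb_modes(m, rep(1L, nrow(xyz)))
  expect_equal(length(rm_$frequencies), 6)
  expect_equal(rm_$n_zero_modes, 6)
})

test_that("RTB eigenvalues dominate the full spectrum index by index", {
  uv <- make_u_v_pair(complex_spec())
  m <- enm(uv$u)
  bl <- blocks_by_chain(uv$u)
  expect_equal(max(bl), 10)              # ten helices, one block each
  rm_ <- rtb_modes(m, bl)
  fm <- full_modes(m, length(rm_$frequencies))
  expect_true(all(rm_$frequencies >= fm$frequencies - 1e-9))
  expect_equal(rm_$n_zero_modes, 6)
  # back-projected modes stay orthonormal
  G <- crossprod(rm_$vectors)
  expect_close(G, diag(ncol(G)), 1e-8)
})

test_that("per-helix RTB reproduces the softest mode of a 4-helix bundle", {
  hs <- list(helix_spec(20, axis_origin = c(0, 0, 0), chain = "A"),
             helix_spec(20, axis_origin = c(8, 0, 0), chain = "B", phase = 90),
             helix_spec(20, axis_origin = c(0, 8, 0), chain = "C", phase = 180),
             helix_spec(20, axis_origin = c(8, 8, 0), chain = "D", phase = 270))
  at <- do.call(rbind, lapply(hs, function(s) make_helix(s)$atoms))
  at$serial <- seq_len(nrow(at))
  bundle <- pdb_structure(at)
  m <- enm(bundle)
  expect_equal(m$n_components, 1)
  fm <- full_modes(m, 8)
  rm_ <- rtb_modes(m, blocks_by_chain(bundle), 8)
  i <- 7                                  # first nonzero mode
  expect_gte(abs(sum(fm$vectors[, i] * rm_$vectors[, i])), 0.9)
})

test_that("the spectrum is invariant under node reordering and rigid motion", {
  xyz <- coords(make_helix(helix_spec(14)))
  m <- enm(xyz)
  ev <- full_modes(m, 12)$frequencies
  set.seed(3)
  perm <- sample(nrow(xyz))
  ev_p <- full_modes(enm(xyz[perm, ]), 12)$frequencies
  expect_close(ev, ev_p, 1e-9)
  R <- random_rotation()
  xyz_r <- sweep(xyz %*% t(R), 2, -c(4, 5, 6))
  ms_r <- full_modes(enm(xyz_r), 12)
  expect_close(ev, ms_r$frequencies, 1e-9)
  # first nonzero mode maps through the same rotation (up to sign)
  v <- matrix(full_modes(m, 7)$vectors[, 7], ncol = 3, byrow = TRUE)
  vr <- matrix(ms_r$vectors[, 7], ncol = 3, byrow = TRUE)
  expect_close(abs(sum((v %*% t(R)) * vr)), 1, 1e-6)
})

test_that("model validation catches bad inputs", {
  expect_error(enm(matrix(0, 1, 3)), "at least 2")
  expect_error(enm(rbind(c(0, 0, 0), c(1, 0, 0)), cutoff = -1), "positive")
  m <- enm(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_error(full_modes(m, 10), "exceeds")
  expect_error(rtb_modes(m, c(1L)), "every node")
})
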