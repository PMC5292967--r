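uv_modes_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      uv <- make_u_v_pair(complex_spec())
      m <- enm(uv$u)
      modes <- rtb_modes(m, blocks_by_chain(uv$u))
      cache <<- list(uv = uv, model = m, modes = modes)
    }
    cache
  }
})

test_that("transition vectors remove rigid-body differences first", {
  fx <- uv_modes_fixture()
  u <- fx$uv$u
  tv0 <- transition_vector(u, u)
  expect_equal(tv0$rmsd_initial, 0)
  expect_close(tv0$displacement, 0, 1e-12)
  # a purely rigid difference vanishes after the frame fit
  R <- rotation_matrix(c(1, 2, 2) / 3, 23)
  u_rot <- apply_transform(u, list(rotation = R, translation = c(5, -1, 2)))
  expect_close(transition_vector(u, u_rot)$rmsd_initial, 0, 1e-9)
  # planted exact-amplitude transition
  v29 <- scale_transition(u, fx$uv$v, 2.9, frame_selection = tm1_frame())
  expect_close(transition_vector(u, v29,
                                 frame_selection = tm1_frame())$rmsd_initial,
               2.9, 1e-6)
})

test_that("mode overlaps obey the closed forms on constructed displacements", {
  fx <- uv_modes_fixture()
  modes <- fx$modes
  idx <- modes$n_zero_modes + 1:12
  m1 <- modes$vectors[, idx[1]]
  m2 <- modes$vectors[, idx[2]]
  ov <- mode_overlap(m1, modes)
  expect_close(ov$per_mode[1], 1, 1e-9)
  expect_close(ov$per_mode[-1], 0, 1e-9)
  ov2 <- mode_overlap((m1 + m2) / sqrt(2), modes)
  expect_close(ov2$per_mode[1:2], sqrt(0.5), 1e-9)
  expect_close(ov2$cumulative[2], 1, 1e-9)
  # any displacement inside the span of the 10 lowest modes is fully
  # explained by them
  set.seed(8)
  d <- modes$vectors[, idx[1:10]] %*% stats::rnorm(10)
  ovr <- mode_overlap(d, modes)
  expect_close(ovr$cumulative[10], 1, 1e-9)
  expect_true(all(diff(ovr$cumulative) >= -1e-12))
  expect_true(all(ovr$cumulative <= 1 + 1e-9))
  expect_error(mode_overlap(numeric(length(m1)), modes), "zero displacement")
})

test_that("best-k fits decompose the transition orthogonally", {
  fx <- uv_modes_fixture()
  modes <- fx$modes
  tv <- transition_vector(fx$uv$u, fx$uv$v, frame_selection = tm1_frame())
  n_nz <- length(modes$frequencies) - modes$n_zero_modes
  for (k in c(0, 3, 10, n_nz)) {
    fit <- best_k_fit(tv$displacement, modes, k)
    expect_close(tv$rmsd_initial^2,
                 fit$rmsd_explained^2 + fit$rmsd_residual^2, 1e-6)
    expect_lte(fit$rmsd_residual, tv$rmsd_initial + 1e-12)
  }
  expect_close(best_k_fit(tv$displacement, modes, 0)$rmsd_residual,
               tv$rmsd_initial, 1e-12)
  expect_error(best_k_fit(tv$displacement, modes, n_nz + 1), "exceeds")
  # residuals shrink monotonically with k
  res <- vapply(1:15, function(k)
    best_k_fit(tv$displacement, modes, k)$rmsd_residual, numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("a planted 0.96/0.28 split yields exactly that residual fraction", {
  fx <- uv_modes_fixture()
  modes <- fx$modes
  idx <- modes$n_zero_modes + 1:4
  inside <- modes$vectors[, idx[1:3]] %*% c(0.5, 0.4, 0.3)
  inside <- inside / sqrt(sum(inside^2))
  outside <- modes$vectors[, idx[4]]     # orthogonal to the first 3 modes
  d <- 0.96 * inside + 0.28 * outside
  fit <- best_k_fit(d, modes, 3)
  n_atoms <- length(d) / 3
  expect_close(fit$rmsd_residual / sqrt(sum(d^2) / n_atoms), 0.28, 1e-6)
})

test_that("a transition planted along one mode is attributed to that mode", {
  fx <- uv_modes_fixture()
  modes <- fx$modes
  i3 <- modes$n_zero_modes + 3
  u <- fx$uv$u
  v <- u
  disp <- 1.7 * matrix(modes$vectors[, i3], ncol = 3, byrow = TRUE)
  v <- set_coords(v, coords(v) + disp)
  tv <- transition_vector(u, v)
  ov <- mode_overlap(tv$displacement, modes)
  expect_gte(ov$per_mode[3], 0.999)
  fit <- best_k_fit(tv$displacement, modes, 3)
  expect_lt(fit$rmsd_residual / tv$rmsd_initial, 0.01)
})

test_that("mode character separates translation, rotation and deformation", {
  set.seed(13)
  nodes <- matrix(stats::rnorm(60, sd = 6), 20, 3)
  groups <- list(g = 1:20)
  # pure translation
  vt <- rep(c(1, 0, 0) / sqrt(20), 20)
  ch <- classify_mode(vt, nodes, groups)
  expect_close(ch$translation_fraction, 1, 1e-9)
  expect_close(ch$rotation_fraction, 0, 1e-9)
  expect_close(ch$piston, 0, 1e-9)
  # translation along the membrane normal carries piston
  vz <- rep(c(0, 0, 1) / sqrt(20), 20)
  expect_close(classify_mode(vz, nodes, groups)$piston, 1 / sqrt(20), 1e-9)
  # pure infinitesimal rotation about the centroid
  ctr <- colMeans(nodes)
  om <- c(0.2, -0.1, 0.3)
  vr <- t(apply(nodes, 1, function(r) uvshape:::crossprod_vec(om, r - ctr)))
  ch <- classify_mode(as.numeric(t(vr)), nodes, groups)
  expect_close(ch$rotation_fraction, 1, 1e-6)
  expect_close(ch$translation_fraction, 0, 1e-6)
  # mixed screw field splits by the planted norms
  vmix <- as.numeric(t(vr + matrix(c(0.1, 0, 0), 20, 3, byrow = TRUE)))
  ch <- classify_mode(vmix, nodes, groups)
  n2r <- sum(vr^2); n2t <- 20 * 0.01
  expect_close(ch$rotation_fraction, n2r / (n2r + n2t), 1e-3)
  expect_close(ch$translation_fraction, n2t / (n2r + n2t), 1e-3)
  expect_error(classify_mode(vt, nodes, list(tiny = 1:2)), "fewer than 3")
})

test_that("mode displacement is linear and invertible", {
  fx <- uv_modes_fixture()
  u <- fx$uv$u; modes <- fx$modes
  s0 <- displace_along_modes(u, modes, numeric(0), amplitude = 0)
  expect_identical(coords(s0), coords(u))
  # displacing by the best-k fit reproduces V up to exactly the residual
  tv <- transition_vector(u, fx$uv$v, frame_selection = tm1_frame())
  fit <- best_k_fit(tv$displacement, modes, 10)
  vlike <- displace_along_modes(u, modes, fit$coefficients,
                                mode_index = fit$mode_index)
  v_target <- set_coords(u, tv$xyz_u + matrix(tv$displacement, ncol = 3,
                                              byrow = TRUE))
  expect_close(rmsd(coords(vlike), coords(v_target)), fit$rmsd_residual, 1e-9)
  # projecting the generated displacement recovers the coefficients
  d2 <- as.numeric(t(coords(vlike) - coords(u)))
  fit2 <- best_k_fit(d2, modes, 10)
  expect_close(fit2$coefficients, fit$coefficients, 1e-9)
})

test_that("ten soft modes explain most of a planted opening transition", {
  fracs <- vapply(1:5, function(seed) {
    uv <- make_u_v_pair(complex_spec(noise_sigma = 0.1, seed = seed))
    m <- enm(uv$u)
    modes <- rtb_modes(m, blocks_by_chain(uv$u))
    tr <- transition_report(uv$u, uv$v, modes, k = 10,
                            frame_selection = tm1_frame())
    tr$rmsd_residual / tr$rmsd_initial
  }, numeric(1))
  expect_true(all(fracs < 0.35))
})

test_that("the soft modes of the complex are inter-subunit rigid motions", {
  fx <- uv_modes_fixture()
  at <- fx$uv$u$atoms
  groups <- lapply(fx$uv$ground_truth$groups,
                   function(chs) which(at$chain %in% chs))
  i1 <- fx$modes$n_zero_modes + 1
  ch <- classify_mode(fx$modes$vectors[, i1], fx$model$nodes, groups,
                      fx$uv$ground_truth$frame)
  # the receptors move almost rigidly in the softest mode
  rec <- ch[ch$group %in% c("receptor_A", "receptor_B"), ]
  expect_true(all(rec$internal_fraction < 0.1))
})
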