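test_that("helix axis fitting recovers direction, radius and polarity", {
  h <- make_helix(helix_spec(19))             # full turns: axis exact
  ax <- fit_helix_axis(h, "A", 1:19)
  expect_close(abs(ax$direction[3]), 1, 1e-4)
  expect_gt(ax$direction[3], 0)               # oriented N -> C
  h20 <- make_helix(helix_spec(20))
  ax20 <- fit_helix_axis(h20, "A", 1:20)
  expect_lt(abs(ax20$fit_rms - 2.3) / 2.3, 0.05)
  # reversed helix points the other way
  hrev <- make_helix(helix_spec(19, axis_direction = c(0, 0, -1)))
  expect_lt(fit_helix_axis(hrev, "A", 1:19)$direction[3], 0)
  # preconditions
  expect_error(fit_helix_axis(h, "A", 1:4), "at least 5")
  blob <- h
  set.seed(5)
  blob$atoms[c("x", "y", "z")] <- matrix(stats::rnorm(57), ncol = 3)
  expect_error(fit_helix_axis(blob, "A", 1:19), "ill-defined")
})

test_that("inter-helix angles are exact for planted tilts", {
  z <- c(0, 0, 1)
  expect_equal(interhelix_angle(z, z), 0)
  tilt <- c(sin(11 * pi / 180), 0, cos(11 * pi / 180))
  expect_close(interhelix_angle(z, tilt), 11, 1e-9)
  expect_close(interhelix_angle(tilt, z), 11, 1e-9)   # symmetric
  # antiparallel: 180 directed, 0 undirected
  expect_close(interhelix_angle(z, -z), 180, 1e-9)
  expect_close(interhelix_angle(z, -z, directed = FALSE), 0, 1e-9)
  # through fitted axes on full-turn helices
  h1 <- make_helix(helix_spec(19, chain = "A"))
  h2 <- make_helix(helix_spec(19, axis_direction = tilt,
                              axis_origin = c(12, 0, 0), chain = "B"))
  at <- rbind(h1$atoms, h2$atoms); at$serial <- seq_len(nrow(at))
  s <- pdb_structure(at)
  expect_close(interhelix_angle(fit_helix_axis(s, "A", 1:19),
                                fit_helix_axis(s, "B", 1:19)), 11, 1e-4)
})

test_that("piston and axial rotation decouple for planted screw motions", {
  h <- make_helix(helix_spec(26))
  f <- membrane_frame()
  expect_equal(piston_displacement(h, h, "A", 1:26, f), 0)
  expect_equal(helix_axial_rotation(h, h, "A", 1:26), 0)
  set.seed(42)
  for (i in 1:10) {
    theta <- stats::runif(1, 0, 40)
    d <- stats::runif(1, 0, 2)
    R <- rotation_matrix(c(0, 0, 1), theta)
    h2 <- apply_transform(h, list(rotation = R, translation = c(0, 0, d)))
    expect_close(helix_axial_rotation(h, h2, "A", 1:26), theta, 1e-3)
    expect_close(piston_displacement(h, h2, "A", 1:26, f, end = "whole"),
                 d, 1e-9)
    expect_close(piston_displacement(h, h2, "A", 1:26, f), d, 1e-9)
  }
  expect_error(piston_displacement(h, h, "A", 500:510, f), "empty")
})

test_that("the cytoplasmic helix end is identified from the frame", {
  h <- make_helix(helix_spec(24))
  f <- membrane_frame(c(0, 0, 1))
  # displace only the top (intracellular) quarter
  top <- atom_select(chain = "A", resno = 19:24)
  h2 <- apply_transform(h, list(rotation = diag(3),
                                translation = c(0, 0, 0.8)), top)
  expect_close(piston_displacement(h, h2, "A", 1:24, f, end = "cytoplasmic"),
               0.8, 1e-9)
  expect_close(piston_displacement(h, h2, "A", 1:24, f, end = "extracellular"),
               0, 1e-9)
  # flipping the frame swaps the ends
  fdown <- membrane_frame(c(0, 0, -1))
  expect_close(piston_displacement(h, h2, "A", 1:24, fdown, end = "cytoplasmic"),
               0, 1e-9)
})

test_that("contact typing follows the distance and role thresholds", {
  # Lys side-chain nitrogen against Asp carboxylate at varying distance
  fx <- function(d) {
    a <- micro_atoms(atm("NZ", "LYS", 1, c(0, 0, 0)),
                     atm("CE", "LYS", 1, c(-1.5, 0, 0)))
    b <- micro_atoms(atm("OD1", "ASP", 9, c(d, 0, 0), chain = "B"))
    detect_contacts(a, b, same_structure = FALSE)
  }
  pick <- function(ct) ct$kind[ct$name_a == "NZ"]
  expect_equal(pick(fx(3.8)), "salt_bridge")
  expect_equal(pick(fx(4.4)), "contact")     # beyond 4.0: no salt bridge
  expect_equal(pick(fx(2.0)), "clash")
  expect_equal(nrow(fx(5.0)), 0)             # beyond 4.5: no record
  # hydrogen bond with donor-antecedent geometry
  hb <- function(acc_xyz) {
    a <- micro_atoms(atm("OG", "SER", 1, c(0, 0, 0)),
                     atm("CB", "SER", 1, c(-1.5, 0, 0)))
    b <- micro_atoms(atm("O", "GLY", 9, acc_xyz, chain = "B"))
    detect_contacts(a, b, same_structure = FALSE)
  }
  good <- hb(c(3.0, 0, 0))                   # antecedent-donor-acceptor 180
  good <- good[good$name_a == "OG", ]
  expect_equal(good$kind, "hydrogen_bond")
  expect_close(good$angle, 180, 1e-6)
  bad <- hb(c(-1.0, 2.6, 0))                 # angle well under 90
  expect_false(any(bad$kind == "hydrogen_bond"))
  # Calpha-only input: kinds restricted, with a warning
  h <- make_helix(helix_spec(8))
  h2 <- apply_transform(h, list(rotation = diag(3), translation = c(2, 0, 0)))
  expect_warning(ct <- detect_contacts(h, h2, same_structure = FALSE),
                 "Calpha-only")
  expect_true(all(ct$kind %in% c("clash", "contact")))
})

test_that("contact detection is symmetric and rigid-motion invariant", {
  uv <- make_u_v_pair(complex_spec())
  a <- select_atoms(uv$u, atom_select(chain = "B"))
  b <- select_atoms(uv$u, atom_select(chain = "D"))
  ab <- suppressWarnings(detect_contacts(a, b, same_structure = FALSE))
  ba <- suppressWarnings(detect_contacts(b, a, same_structure = FALSE))
  expect_gt(nrow(ab), 0)
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(sort(ab$distance), sort(ba$distance))
  R <- rotation_matrix(c(1, 1, 0) / sqrt(2), 37)
  tf <- list(rotation = R, translation = c(3, -2, 7))
  ab2 <- suppressWarnings(
    detect_contacts(apply_transform(a, tf), apply_transform(b, tf),
                    same_structure = FALSE))
  expect_equal(nrow(ab2), nrow(ab))
  expect_close(sort(ab2$distance), sort(ab$distance), 1e-9)
})
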