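# Shared fixture builders; everything is generated in code at test time.

two_helix_structure <- function(n = 12) {
  a <- make_helix(helix_spec(n, chain = "A"))
  b <- make_helix(helix_spec(n, axis_origin = c(9, 0, 0), chain = "B",
                             phase = 60))
  at <- rbind(a$atoms, b$atoms)
  at$serial <- seq_len(nrow(at))
  pdb_structure(at, label = "two-helix fixture")
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  rotation_matrix(axis / sqrt(sum(axis^2)), stats::runif(1, 1, 179))
}

# Minimal all-atom builder for contact-typing tests: each row one atom.
micro_atoms <- function(...) {
  rows <- list(...)
  at <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, resid = r$resid,
               chain = if (is.null(r$chain)) "A" else r$chain,
               resno = r$resno, ins = "",
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               o = 1, b = 0,
               element = substr(gsub("[0-9]", "", r$name), 1, 1),
               type = "ATOM", stringsAsFactors = FALSE)
  }))
  pdb_structure(at, label = "micro fixture")
}

atm <- function(name, resid, resno, xyz, chain = "A") {
  list(name = name, resid = resid, resno = resno, xyz = xyz, chain = chain)
}

# Frame selection that only contains atoms no perturbation ever touches
# (both TM1 helices); using it makes planted transforms exactly
# recoverable.
tm1_frame <- function() atom_select(chain = c("B", "D"), resno = 1:26,
                                    name = "CA")

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
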