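#' Atomic structure container
#'
#' A `pdb_structure` holds an ordered atom table plus optional crystal
#' metadata. Atoms live in a data frame with one row per atom and columns
#' `serial`, `name`, `resid` (3-letter residue name), `chain`, `resno`,
#' `ins` (insertion code, `""` when absent), `x`, `y`, `z` (angstrom),
#' `o` (occupancy), `b` (B-factor, A^2), `element` and `type`
#' (`"ATOM"`/`"HETATM"`). `cell` is `NULL` or the six cell constants
#' (a, b, c in angstrom; alpha, beta, gamma in degrees) and `space_group`
#' is `NULL` or a Hermann-Mauguin symbol.
#'
#' @param atoms atom data frame as described above
#' @param cell numeric length-6 unit cell or NULL
#' @param space_group Hermann-Mauguin symbol or NULL
#' @param label free-text label carried through reports
#' @return an object of class `pdb_structure`
#' @export
pdb_structure <- function(atoms, cell = NULL, space_group = NULL, label = "") {
  required <- c("serial", "name", "resid", "chain", "resno", "ins",
                "x", "y", "z", "o", "b", "element", "type")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) && !all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite atom coordinates")
  if (nrow(atoms) && (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)))
    stop("occupancy outside [0, 1]")
  if (!is.null(space_group) && is.null(cell))
    stop("space_group given without unit_cell")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6 || !all(is.finite(cell)) || any(cell[1:3] <= 0))
      stop("unit cell must be 6 finite numbers with positive edge lengths")
  }
  structure(list(atoms = atoms, cell = cell, space_group = space_group,
                 label = label),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat("pdb_structure", if (nzchar(x$label)) paste0("'", x$label, "'"), "\n")
  cat("  atoms:   ", nrow(x$atoms), " (chains: ",
      paste(unique(x$atoms$chain), collapse = " "), ")\n", sep = "")
  if (!is.null(x$cell))
    cat("  cell:    ", paste(format(x$cell, digits = 6), collapse = " "),
        "  ", if (is.null(x$space_group)) "" else x$space_group, "\n", sep = "")
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param structure a `pdb_structure`
#' @param selection optional `atom_selection` (see [atom_select()])
#' @return an n x 3 numeric matrix of coordinates in angstrom
#' @export
coords <- function(structure, selection = NULL) {
  at <- structure$atoms
  if (!is.null(selection)) at <- at[selection_mask(structure, selection), , drop = FALSE]
  m <- cbind(at$x, at$y, at$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace the coordinates of a structure
#'
#' @param structure a `pdb_structure`
#' @param xyz n x 3 matrix matching the atom count (or the selection's count)
#' @param selection optional `atom_selection` restricting which atoms change
#' @return the modified structure
#' @export
set_coords <- function(structure, xyz, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(nrow(structure$atoms))
         else which(selection_mask(structure, selection))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != length(idx)) stop("coordinate count mismatch")
  structure$atoms$x[idx] <- xyz[, 1]
  structure$atoms$y[idx] <- xyz[, 2]
  structure$atoms$z[idx] <- xyz[, 3]
  structure
}

# Fixed-width PDB column slices, 1-based inclusive.
.substr_num <- function(line, from, to, what, lineno) {
  s <- trimws(substr(line, from, to))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    stop(sprintf("malformed %s field in PDB record at line %d: '%s'",
                 what, lineno, s), call. = FALSE)
  v
}

#' Read a PDB file
#'
#' Parses fixed-width `ATOM`/`HETATM` records into an atom table and
#' `CRYST1` into unit-cell + space-group metadata. Only the first
#' alternate location (blank or `'A'`) of each atom is kept, giving a
#' deterministic single-conformer model. A missing `CRYST1` record is not
#' an error; the structure simply has no cell. Malformed numeric fields
#' raise an error naming the offending line.
#'
#' @param path path to a PDB-format file
#' @param label optional label; defaults to the file name
#' @return a [pdb_structure()]
#' @export
read_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  cell <- NULL; sg <- NULL
  icr <- which(rec == "CRYST1")
  if (length(icr)) {
    l <- lines[icr[1]]; n <- icr[1]
    cell <- c(.substr_num(l, 7, 15, "cell a", n),
              .substr_num(l, 16, 24, "cell b", n),
              .substr_num(l, 25, 33, "cell c", n),
              .substr_num(l, 34, 40, "cell alpha", n),
              .substr_num(l, 41, 47, "cell beta", n),
              .substr_num(l, 48, 54, "cell gamma", n))
    sg <- trimws(substr(l, 56, 66))
    if (!nzchar(sg)) sg <- NULL
  }
  idx <- which(is_atom)
  if (!length(idx)) {
    atoms <- empty_atom_table()
    return(pdb_structure(atoms, cell, sg, label))
  }
  al <- lines[idx]
  altloc <- substr(al, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  al <- al[keep]; idx <- idx[keep]
  n <- length(al)
  x <- numeric(n); y <- numeric(n); z <- numeric(n)
  o <- numeric(n); b <- numeric(n); serial <- integer(n); resno <- integer(n)
  for (i in seq_len(n)) {
    serial[i] <- as.integer(.substr_num(al[i], 7, 11, "serial", idx[i]))
    resno[i]  <- as.integer(.substr_num(al[i], 23, 26, "residue number", idx[i]))
    x[i] <- .substr_num(al[i], 31, 38, "x", idx[i])
    y[i] <- .substr_num(al[i], 39, 46, "y", idx[i])
    z[i] <- .substr_num(al[i], 47, 54, "z", idx[i])
    os <- trimws(substr(al[i], 55, 60))
    o[i] <- if (nzchar(os)) .substr_num(al[i], 55, 60, "occupancy", idx[i]) else 1
    bs <- trimws(substr(al[i], 61, 66))
    b[i] <- if (nzchar(bs)) .substr_num(al[i], 61, 66, "b-factor", idx[i]) else 0
  }
  atoms <- data.frame(
    serial = serial,
    name = trimws(substr(al, 13, 16)),
    resid = trimws(substr(al, 18, 20)),
    chain = substr(al, 22, 22),
    resno = resno,
    ins = trimws(substr(al, 27, 27)),
    x = x, y = y, z = z, o = pmin(pmax(o, 0), 1), b = b,
    element = trimws(substr(al, 77, 78)),
    type = ifelse(substr(al, 1, 4) == "ATOM", "ATOM", "HETATM"),
    stringsAsFactors = FALSE)
  blank <- !nzchar(atoms$element)
  if (any(blank))  # fall back on the first letter of the atom name
    atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$name[blank]), 1, 1)
  pdb_structure(atoms, cell, sg, label)
}

empty_atom_table <- function() {
  data.frame(serial = integer(), name = character(), resid = character(),
             chain = character(), resno = integer(), ins = character(),
             x = numeric(), y = numeric(), z = numeric(),
             o = numeric(), b = numeric(), element = character(),
             type = character(), stringsAsFactors = FALSE)
}

# PDB atom-name field: names shorter than 4 characters start in column 14
# unless they begin with a 2-letter element symbol.
.format_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         formatC(paste0(" ", name), width = -4))
}

#' Write a PDB file
#'
#' Emits standard fixed-width `ATOM`/`HETATM` records (coordinates to
#' three decimals), a `CRYST1` record when the structure carries a cell,
#' `TER` records at chain breaks, and `END`. Coordinates with magnitude
#' >= 1e4 angstrom do not fit the 8.3 field and raise an error.
#'
#' @param structure a [pdb_structure()]
#' @param path output file path
#' @return invisibly, the path
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  if (nrow(at)) {
    if (!all(is.finite(c(at$x, at$y, at$z)))) stop("non-finite coordinates")
    if (max(abs(c(at$x, at$y, at$z))) >= 1e4)
      stop("coordinate magnitude >= 1e4 A cannot be formatted in PDB fields")
  }
  out <- character(0)
  if (!is.null(structure$cell)) {
    sg <- if (is.null(structure$space_group)) "P 1" else structure$space_group
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                          structure$cell[1], structure$cell[2], structure$cell[3],
                          structure$cell[4], structure$cell[5], structure$cell[6],
                          sg, 1L))
  }
  if (nrow(at)) {
    recs <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    at$type, at$serial %% 100000L, .format_atom_name(at$name), "",
                    at$resid, at$chain, at$resno,
                    ifelse(nzchar(at$ins), at$ins, " "),
                    at$x, at$y, at$z, at$o, at$b,
                    formatC(at$element, width = 2))
    # TER after each chain's last atom
    brk <- which(at$chain[-1] != at$chain[-nrow(at)])
    pieces <- split(seq_len(nrow(at)), cumsum(seq_len(nrow(at)) %in% (brk + 1L)))
    for (p in pieces) out <- c(out, recs[p], "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
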