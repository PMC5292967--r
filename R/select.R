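#' Atom selections
#'
#' An `atom_selection` is a predicate over chain IDs, residue-number
#' ranges and atom names. Applying a selection never reorders atoms.
#'
#' @param chain character vector of chain IDs to keep, or NULL for all
#' @param resno integer vector of residue numbers to keep (build ranges
#'   with `:` or [seq()]), or NULL for all
#' @param name atom-name set (e.g. `"CA"` for Calpha only), or NULL
#' @param type `"ATOM"`, `"HETATM"` or NULL for both
#' @return an object of class `atom_selection`
#' @examples
#' ca <- atom_select(name = "CA")
#' recA <- atom_select(chain = "A", resno = 201:222, name = "CA")
#' @export
atom_select <- function(chain = NULL, resno = NULL, name = NULL, type = NULL) {
  structure(list(chain = chain, resno = resno, name = name, type = type),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  f <- function(v) if (is.null(v)) "*" else paste(v, collapse = ",")
  cat("atom_selection: chain", f(x$chain), "| resno", f(x$resno),
      "| name", f(x$name), "| type", f(x$type), "\n")
  invisible(x)
}

#' Logical mask of a selection over a structure's atoms
#'
#' @param structure a [pdb_structure()]
#' @param selection an [atom_select()] object (NULL keeps everything)
#' @return logical vector, one entry per atom, in atom order
#' @export
selection_mask <- function(structure, selection = NULL) {
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (is.null(selection)) return(keep)
  if (!inherits(selection, "atom_selection")) stop("not an atom_selection")
  if (!is.null(selection$chain)) keep <- keep & at$chain %in% selection$chain
  if (!is.null(selection$resno)) keep <- keep & at$resno %in% selection$resno
  if (!is.null(selection$name))  keep <- keep & at$name %in% selection$name
  if (!is.null(selection$type))  keep <- keep & at$type %in% selection$type
  keep
}

#' Subset a structure by a selection
#'
#' @inheritParams selection_mask
#' @return a [pdb_structure()] containing only the selected atoms
#' @export
select_atoms <- function(structure, selection) {
  structure$atoms <- structure$atoms[selection_mask(structure, selection), ,
                                     drop = FALSE]
  rownames(structure$atoms) <- NULL
  structure
}

#' Pair the atoms common to two structures
#'
#' Matches atoms by (chain, residue number, insertion code, atom name)
#' present in both structures after applying `selection`, the standard
#' precondition of any cross-conformation RMSD: only residues resolved in
#' both models contribute. An optional `chain_map` renames chains of `a`
#' before matching, for comparing depositions with different chain
#' labelling.
#'
#' @param a,b [pdb_structure()] objects
#' @param selection optional [atom_select()] applied to both structures
#' @param chain_map optional named character vector mapping chain IDs of
#'   `a` to chain IDs of `b`, e.g. `c(A = "C")`
#' @return a list with `xyz_a`, `xyz_b` (paired n x 3 coordinate
#'   matrices, in `a`'s atom order) and `atoms` (the matched identity
#'   table from `a`)
#' @export
pair_common_atoms <- function(a, b, selection = NULL, chain_map = NULL) {
  if (!nrow(a$atoms) || !nrow(b$atoms)) stop("empty structure")
  aa <- a$atoms[selection_mask(a, selection), , drop = FALSE]
  bb <- b$atoms[selection_mask(b, selection), , drop = FALSE]
  chain_a <- aa$chain
  if (!is.null(chain_map)) {
    hit <- chain_a %in% names(chain_map)
    chain_a[hit] <- unname(chain_map[chain_a[hit]])
  }
  key_a <- paste(chain_a, aa$resno, aa$ins, aa$name, sep = "|")
  key_b <- paste(bb$chain, bb$resno, bb$ins, bb$name, sep = "|")
  m <- match(key_a, key_b)
  keep <- !is.na(m)
  if (!any(keep))
    stop("no atoms in common between the two structures under this selection")
  ia <- which(keep); ib <- m[keep]
  list(xyz_a = cbind(x = aa$x[ia], y = aa$y[ia], z = aa$z[ia]),
       xyz_b = cbind(x = bb$x[ib], y = bb$y[ib], z = bb$z[ib]),
       atoms = aa[ia, c("chain", "resno", "ins", "name", "resid"), drop = FALSE])
}
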