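#' Atom tables and peptide fragments
#'
#' Throughout the package an atomic model is a tibble with one row per atom
#' ("atom table"): columns `resid` (integer residue number), `resname`
#' (3-letter residue name), `atom` (PDB atom name), `element` (C/N/O/S),
#' `x`, `y`, `z` (Cartesian angstroms), `b` (isotropic B factor, A^2) and
#' `occ` (occupancy, fixed at 1). A *fragment* is an atom table whose
#' residues are contiguous and carries a `source_id` attribute.
#'
#' @name atom-tables
NULL

#' Chemical elements supported by the scattering model
#' @keywords internal
SUPPORTED_ELEMENTS <- c("C", "N", "O", "S")

#' Atomic masses used for centre-of-mass computations (heavy atoms only)
#' @keywords internal
ELEMENT_MASS <- c(C = 12, N = 14, O = 16, S = 32)

#' The 20 standard amino-acid 3-letter codes
#' @keywords internal
STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Expected heavy atoms per standard residue
#'
#' Used by [clean_fragment()] to detect missing atoms. Full heavy-atom
#' complements per PDB chemical component definitions (no hydrogens, no OXT).
#' @keywords internal
RESIDUE_HEAVY_ATOMS <- list(
  GLY = c("N", "CA", "C", "O"),
  ALA = c("N", "CA", "C", "O", "CB"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3",
          "CZ2", "CZ3", "CH2"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD")
)

#' Construct a fragment from an atom table
#'
#' Validates the atom-table contract and attaches provenance. Residue
#' numbers must be strictly increasing and contiguous within the fragment.
#'
#' @param atoms data frame with columns `resid`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `b`, and optionally `occ` (defaults to 1).
#' @param source_id free-text provenance tag.
#' @return a fragment: a tibble of atoms with attribute `source_id`.
#' @export
new_fragment <- function(atoms, source_id = "synthetic") {
  req <- c("resid", "resname", "atom", "element", "x", "y", "z", "b")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("atom table lacks columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  atoms <- tibble::as_tibble(atoms)
  if (!"occ" %in% names(atoms)) atoms$occ <- 1.0
  if (nrow(atoms) == 0) rlang::abort("fragment must contain at least one atom")
  if (any(!atoms$element %in% SUPPORTED_ELEMENTS)) {
    rlang::abort(paste0("unsupported element(s): ",
                        paste(unique(setdiff(atoms$element, SUPPORTED_ELEMENTS)),
                              collapse = ", ")))
  }
  if (any(atoms$b < 0)) rlang::abort("negative B factor")
  if (any(atoms$occ != 1.0)) rlang::abort("occupancies must all be 1.0")
  rid <- unique(atoms$resid)
  if (length(rid) > 1 && !all(diff(rid) == 1L)) {
    rlang::abort("residue numbers must be strictly increasing and contiguous")
  }
  attr(atoms, "source_id") <- source_id
  class(atoms) <- unique(c("xtal_fragment", class(atoms)))
  atoms
}

#' @export
print.xtal_fragment <- function(x, ...) {
  cat(sprintf("<fragment '%s': %d residues, %d atoms>\n",
              attr(x, "source_id") %||% "?",
              length(unique(x$resid)), nrow(x)))
  NextMethod()
}

#' Number of residues in a fragment
#' @param fragment an atom table.
#' @export
n_residues <- function(fragment) length(unique(fragment$resid))

#' Coordinates of an atom table as an n x 3 matrix
#' @param atoms atom table.
#' @return numeric matrix with columns x, y, z.
#' @export
coords_matrix <- function(atoms) {
  cbind(x = atoms$x, y = atoms$y, z = atoms$z)
}

#' Replace coordinates of an atom table from an n x 3 matrix
#' @keywords internal
set_coords <- function(atoms, m) {
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  atoms
}

#' Mass-weighted centre of mass over heavy atoms
#'
#' Masses: C = 12, N = 14, O = 16, S = 32.
#' @param atoms atom table.
#' @return length-3 numeric (x, y, z), angstroms.
#' @export
centre_of_mass <- function(atoms) {
  w <- ELEMENT_MASS[atoms$element]
  colSums(coords_matrix(atoms) * w) / sum(w)
}

#' Max-min coordinate extents of an atom table
#' @param atoms atom table.
#' @return length-3 numeric, angstroms per axis.
#' @export
extents <- function(atoms) {
  m <- coords_matrix(atoms)
  apply(m, 2, max) - apply(m, 2, min)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
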