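#' Unit cells and crystal symmetry
#'
#' Orthogonal-axis unit cells (all angles 90 degrees) in space group P1 or
#' P21. A P21 cell with beta = 90 is a valid monoclinic setting; the
#' two-fold screw axis runs along axis 2 through fractional (0, y, 0) by
#' convention. Cells are built around a single fragment whose mass-weighted
#' centre of mass sits at the exact cell centre, which pins down the
#' otherwise arbitrary origin of the translation-invariant Patterson map.
#'
#' @name crystal
NULL

#' Construct a unit-cell model
#'
#' @param atoms atom table in Cartesian angstroms; must carry an integer
#'   `copy` column identifying the symmetry copy (1-based).
#' @param cell length-3 numeric, axis lengths in angstroms.
#' @param space_group `"P1"` or `"P21"`.
#' @param screw_multiplier the axis-2 expansion multiplier applied at P21
#'   conversion (NA for P1 cells).
#' @return an object of class `unit_cell`.
#' @export
unit_cell <- function(atoms, cell, space_group = c("P1", "P21"),
                      screw_multiplier = NA_real_) {
  space_group <- match.arg(space_group)
  stopifnot(length(cell) == 3, all(cell > 0))
  if (!"copy" %in% names(atoms)) atoms$copy <- 1L
  n_copies <- length(unique(atoms$copy))
  if (space_group == "P21" && n_copies != 2) {
    rlang::abort("a P21 cell must contain exactly two symmetry copies")
  }
  structure(list(cell = as.numeric(cell), angles = c(90, 90, 90),
                 space_group = space_group,
                 atoms = tibble::as_tibble(atoms),
                 screw_multiplier = screw_multiplier),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell %s: a=%.2f b=%.2f c=%.2f A, %d atoms in %d cop%s>\n",
              x$space_group, x$cell[1], x$cell[2], x$cell[3],
              nrow(x$atoms), length(unique(x$atoms$copy)),
              if (length(unique(x$atoms$copy)) == 1) "y" else "ies"))
  invisible(x)
}

#' Cell volume in cubic angstroms
#' @param cell a `unit_cell`.
#' @export
cell_volume <- function(cell) prod(cell$cell)

#' Fractional coordinates of the cell contents
#' @param cell a `unit_cell`.
#' @return n x 3 matrix of fractional coordinates (not wrapped).
#' @export
frac_coords <- function(cell) {
  sweep(coords_matrix(cell$atoms), 2, cell$cell, "/")
}

#' Reorient a fragment so axis extents satisfy e1 >= e3 >= e2
#'
#' Permutes the coordinate axes (with at most one sign flip to keep the
#' transform proper, determinant +1) so that the first axis has the largest
#' max-min extent and the second axis the smallest. Interatomic distances
#' and chirality are preserved exactly.
#'
#' @param fragment an atom table.
#' @return the fragment with permuted coordinates.
#' @export
reorient <- function(fragment) {
  m <- coords_matrix(fragment)
  if (nrow(m) < 2) rlang::abort("cannot reorient a degenerate fragment")
  mc <- sweep(m, 2, colMeans(m))
  if (qr(mc)$rank < 2) {
    rlang::abort("cannot reorient a degenerate (collinear/coincident) fragment")
  }
  e <- extents(fragment)
  ord <- order(e, decreasing = TRUE)        # ord[1] largest ... ord[3] smallest
  perm <- c(ord[1], ord[3], ord[2])         # target order: big, small, middle
  signs <- c(1, 1, 1)
  # permutation sign: +1 for even permutations; odd ones need one reflection
  if (permutation_sign(perm) < 0) signs[3] <- -1
  out <- m[, perm, drop = FALSE]
  out <- sweep(out, 2, signs, "*")
  set_coords(fragment, out)
}

permutation_sign <- function(p) {
  s <- 1
  for (i in 1:2) for (j in (i + 1):3) if (p[i] > p[j]) s <- -s
  s
}

# Minimum distance between two Cartesian coordinate sets.
min_cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  max(min(d2), 0)
}

#' Minimum intermolecular contact distance
#'
#' Scans all neighbour-cell translations in \{-1, 0, 1\}^3 and, in P21, the
#' screw-related copy, returning the smallest atom-atom distance between
#' distinct symmetry/lattice copies (distances within one copy are ignored).
#'
#' @param cell a `unit_cell`.
#' @return distance in angstroms.
#' @export
min_contact <- function(cell) {
  if (nrow(cell$atoms) == 0) rlang::abort("empty cell")
  info <- min_contact_info(cell)
  info$dist
}

# As min_contact but also reports the lattice translation of the closest
# approach, used to decide which axes to grow during cell determination.
min_contact_info <- function(cell) {
  atoms <- cell$atoms
  copies <- split(seq_len(nrow(atoms)), atoms$copy)
  xyz <- coords_matrix(atoms)
  tr <- as.matrix(expand.grid(t1 = -1:1, t2 = -1:1, t3 = -1:1))
  best <- list(dist2 = Inf, translation = c(0L, 0L, 0L))
  for (ci in seq_along(copies)) {
    for (cj in seq_along(copies)) {
      a <- xyz[copies[[ci]], , drop = FALSE]
      b <- xyz[copies[[cj]], , drop = FALSE]
      for (r in seq_len(nrow(tr))) {
        t_int <- tr[r, ]
        if (ci == cj && all(t_int == 0)) next   # within one copy
        if (ci == cj && r > 14) next            # t and -t are symmetric
        d2 <- min_cross_dist2(a, sweep(b, 2, t_int * cell$cell, "+"))
        if (d2 < best$dist2) best <- list(dist2 = d2, translation = t_int)
      }
    }
  }
  list(dist = sqrt(best$dist2), translation = best$translation)
}

#' Determine a P1 cell by iterative contact-driven expansion
#'
#' Starts from the raw max-min coordinate extents along each axis and
#' repeatedly grows the axes implicated in the closest intermolecular
#' contact (those with a non-zero component in the offending lattice
#' translation) by `step` angstroms, until the minimum contact between the
#' fragment and any of its lattice translates is at least `min_contact`.
#' The fragment's centre of mass is placed at the cell centre.
#'
#' @param fragment atom table (reoriented; see [reorient()]).
#' @param min_contact required minimum intermolecular distance, angstroms.
#' @param step per-iteration growth of each implicated axis, angstroms.
#' @return a P1 `unit_cell`.
#' @export
determine_cell <- function(fragment, min_contact = 3.5, step = 0.5) {
  if (min_contact <= 0) rlang::abort("min_contact must be positive")
  lengths <- pmax(extents(fragment), step)
  repeat {
    cell <- center_in_cell(fragment, lengths, "P1")
    info <- min_contact_info(cell)
    if (info$dist >= min_contact) return(cell)
    grow <- info$translation != 0
    if (!any(grow)) grow <- rep(TRUE, 3)    # degenerate same-cell overlap
    lengths[grow] <- lengths[grow] + step
  }
}

# Build a cell of given lengths with the fragment's COM at the centre.
center_in_cell <- function(fragment, lengths, space_group) {
  com <- centre_of_mass(fragment)
  shifted <- set_coords(fragment,
                        sweep(coords_matrix(fragment), 2, lengths / 2 - com, "+"))
  shifted$copy <- 1L
  unit_cell(shifted, lengths, space_group)
}

#' Convert a P1 cell to P21
#'
#' Adds one angstrom to every axis, expands axis 2 by a multiplier drawn
#' uniformly from `mult_range`, re-centres the fragment's centre of mass at
#' the new cell centre, and generates the screw mate by the P21 operator
#' (x, y, z) -> (-x, y + 1/2, -z) in fractional coordinates. No contact
#' re-check is performed: close screw contacts are tolerated by design,
#' which keeps the solvent content realistic.
#'
#' @param cell a P1 `unit_cell` containing one fragment copy.
#' @param seed optional integer seed for the multiplier draw.
#' @param mult_range range of the axis-2 expansion multiplier.
#' @return a P21 `unit_cell` with two symmetry copies; `screw_multiplier`
#'   records the drawn multiplier.
#' @export
to_p21 <- function(cell, seed = NULL, mult_range = c(1.7, 1.95)) {
  if (cell$space_group != "P1") rlang::abort("input cell must be P1")
  if (length(unique(cell$atoms$copy)) != 1) {
    rlang::abort("input cell must contain a single fragment copy")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(1, mult_range[1], mult_range[2])
  new_len <- cell$cell + 1.0
  new_len[2] <- new_len[2] * u
  atoms <- cell$atoms
  com <- centre_of_mass(atoms)
  atoms <- set_coords(atoms,
                      sweep(coords_matrix(atoms), 2, new_len / 2 - com, "+"))
  frac <- sweep(coords_matrix(atoms), 2, new_len, "/")
  mate_frac <- cbind(-frac[, 1], frac[, 2] + 0.5, -frac[, 3]) %% 1
  mate <- atoms
  mate <- set_coords(mate, sweep(mate_frac, 2, new_len, "*"))
  atoms$copy <- 1L
  mate$copy <- 2L
  unit_cell(dplyr::bind_rows(atoms, mate), new_len, "P21",
            screw_multiplier = u)
}

#' Grid of minimum periodic distances to the cell contents
#'
#' For every voxel of an `n1 x n2 x n3` fractional grid over the cell,
#' the minimum-image distance to the nearest atom. Shared by the solvent
#' mask and the in-model evaluation mask.
#'
#' @param cell a `unit_cell`.
#' @param shape integer length-3 grid shape.
#' @return 3D numeric array of distances in angstroms.
#' @export
min_distance_grid <- function(cell, shape) {
  stopifnot(length(shape) == 3, all(shape >= 1))
  frac <- frac_coords(cell) %% 1
  axes <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) / shape[a])
  dmin <- array(Inf, dim = shape)
  for (j in seq_len(nrow(frac))) {
    # per-axis wrapped offsets, then separable squared-distance sum
    dx2 <- lapply(1:3, function(a) {
      d <- abs(axes[[a]] - frac[j, a])
      (pmin(d, 1 - d) * cell$cell[a])^2
    })
    d2 <- outer(outer(dx2[[1]], dx2[[2]], "+"), dx2[[3]], "+")
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Solvent fraction of a unit cell
#'
#' Fraction of grid voxels whose minimum periodic distance to any atom
#' exceeds the mask radius. With no atoms the whole cell is solvent.
#'
#' @param cell a `unit_cell`.
#' @param shape integer length-3 grid shape used for the voxel scan.
#' @param radius mask radius in angstroms (default 2.2, a typical
#'   van-der-Waals-scale mask).
#' @return fraction in `[0, 1]`.
#' @export
solvent_fraction <- function(cell, shape = c(24, 24, 24), radius = 2.2) {
  if (nrow(cell$atoms) == 0) return(1.0)
  mean(min_distance_grid(cell, shape) > radius)
}
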