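#' Dataset-generation pipeline
#'
#' From per-chain coordinates to training records: overlapping 15-residue
#' fragment extraction, cleanup, residue-omitted partial structures,
#' resolution binning, map generation at bin-specific grid shapes, global
#' max-min normalization and shape batching.
#'
#' @name pipeline
NULL

#' Extract overlapping fragments from a chain
#'
#' Windows of `frag_len` residues taken at stride `frag_len - max_overlap`
#' (so consecutive fragments share at most `max_overlap` residues).
#' Trailing residues that cannot form a window without exceeding the
#' overlap cap are dropped.
#'
#' @param chain atom table of one contiguous chain.
#' @param frag_len window length in residues (default 15).
#' @param max_overlap maximum residues shared by consecutive windows.
#' @return list of fragments (possibly empty).
#' @export
extract_fragments <- function(chain, frag_len = 15, max_overlap = 5) {
  rid <- sort(unique(chain$resid))
  n <- length(rid)
  if (n < frag_len) return(list())
  stride <- frag_len - max_overlap
  starts <- seq(1L, n - frag_len + 1L, by = stride)
  src <- attr(chain, "source_id") %||% "chain"
  lapply(seq_along(starts), function(i) {
    keep <- rid[starts[i]:(starts[i] + frag_len - 1L)]
    # all windows keep the parent structure id so train/test splitting can
    # group them; the window start is tracked separately
    out <- new_fragment(chain[chain$resid %in% keep, ], source_id = src)
    attr(out, "window_start") <- starts[i]
    out
  })
}

#' Clean a fragment or reject it
#'
#' Removes hydrogens, converts selenomethionine (MSE) to methionine (Se at
#' atom SD becomes S), and rejects fragments with non-standard residue
#' names, residue-numbering gaps or missing heavy atoms (checked against a
#' bundled per-residue heavy-atom template). B factors are kept as found.
#'
#' @param fragment atom table.
#' @return the cleaned fragment, or `NULL` if the fragment is rejected
#'   (rejection is a signalled outcome, not an error).
#' @export
clean_fragment <- function(fragment) {
  atoms <- fragment[fragment$element != "H" &
                      !grepl("^H|^[0-9]H", fragment$atom), ]
  if (nrow(atoms) == 0) return(NULL)
  mse <- atoms$resname == "MSE"
  if (any(mse)) {
    atoms$resname[mse] <- "MET"
    se_sd <- mse & atoms$atom %in% c("SE", "SD")
    atoms$atom[se_sd] <- "SD"
    atoms$element[se_sd] <- "S"
  }
  if (!all(atoms$resname %in% STANDARD_RESIDUES)) return(NULL)
  rid <- sort(unique(atoms$resid))
  if (length(rid) > 1 && any(diff(rid) != 1L)) return(NULL)
  for (r in rid) {
    rows <- atoms[atoms$resid == r, ]
    template <- RESIDUE_HEAVY_ATOMS[[rows$resname[1]]]
    if (!all(template %in% rows$atom)) return(NULL)
  }
  new_fragment(atoms, source_id = attr(fragment, "source_id") %||% "cleaned")
}

#' Residue-omission partial structures
#'
#' Draws up to `J` partial structures from a 15-residue fragment. Per
#' draw: the end to omit from is uniform over \{start, end, both\} and the
#' omitted count uniform over 3..7; for "both" the count is split floor/ceil
#' with a fair coin deciding which end receives the extra residue when the
#' count is odd. A draw that reproduces an already-generated omitted-residue
#' set is discarded rather than retried, so fewer than `J` partials may
#' result.
#'
#' @param fragment fragment with exactly `frag_len` residues.
#' @param J maximum number of partial structures (default 3).
#' @param seed optional integer seed.
#' @param frag_len required fragment length (default 15).
#' @param n_omit_range inclusive range of omitted residue counts.
#' @return list of `list(fragment =, record =)` where `record` is a tibble
#'   row: `end_choice`, `n_omitted`, `n_start`, `n_end`.
#' @export
make_partials <- function(fragment, J = 3, seed = NULL, frag_len = 15,
                          n_omit_range = c(3, 7)) {
  if (n_residues(fragment) != frag_len) {
    rlang::abort(sprintf("fragment must have %d residues", frag_len))
  }
  if (!is.null(seed)) set.seed(seed)
  rid <- sort(unique(fragment$resid))
  seen <- list()
  out <- list()
  for (draw in seq_len(J)) {
    end_choice <- sample(c("start", "end", "both"), 1)
    n_omit <- sample(seq(n_omit_range[1], n_omit_range[2]), 1)
    if (end_choice == "start") {
      split <- c(n_omit, 0L)
    } else if (end_choice == "end") {
      split <- c(0L, n_omit)
    } else {
      lo <- n_omit %/% 2L
      hi <- n_omit - lo
      split <- if (n_omit %% 2L == 0L) c(lo, hi)
      else if (sample(c(TRUE, FALSE), 1)) c(hi, lo) else c(lo, hi)
    }
    omitted <- c(utils::head(rid, split[1]), utils::tail(rid, split[2]))
    key <- paste(sort(omitted), collapse = ",")
    if (key %in% names(seen)) next   # duplicate pattern: discard, no retry
    seen[[key]] <- TRUE
    part <- new_fragment(fragment[!fragment$resid %in% omitted, ],
                         source_id = paste0(attr(fragment, "source_id") %||%
                                              "frag", "-om", key))
    out[[length(out) + 1]] <- list(
      fragment = part,
      record = tibble::tibble(end_choice = end_choice, n_omitted = n_omit,
                              n_start = split[1], n_end = split[2]))
  }
  out
}

#' Resolution bins
#'
#' Twenty bins spanning resolution limits 1.75-2.3 angstroms paired
#' monotonically with grid-sampling factors 2.29-2.7 (lowest d_min with
#' lowest factor, keeping voxel counts balanced across bins).
#'
#' @param index bin index 0..19 (or an example index; see [assign_bin()]).
#' @param n_bins number of bins.
#' @param d_range resolution-limit range, angstroms.
#' @param f_range sampling-factor range.
#' @return tibble row: `index`, `d_min`, `sampling_factor`.
#' @export
resolution_bin <- function(index, n_bins = 20, d_range = c(1.75, 2.3),
                           f_range = c(2.29, 2.7)) {
  stopifnot(index >= 0, index < n_bins)
  frac <- index / (n_bins - 1)
  tibble::tibble(index = as.integer(index),
                 d_min = d_range[1] + frac * diff(d_range),
                 sampling_factor = f_range[1] + frac * diff(f_range))
}

#' Assign an example to a resolution bin
#'
#' Even division by index modulo the bin count: any run of consecutive
#' example indices fills bins with sizes differing by at most one.
#'
#' @param example_index 0-based example index.
#' @param n_bins number of bins (default 20).
#' @param ... passed to [resolution_bin()].
#' @export
assign_bin <- function(example_index, n_bins = 20, ...) {
  resolution_bin(example_index %% n_bins, n_bins = n_bins, ...)
}

#' Smallest 2,3,5-smooth integer >= n
#' @param n positive number.
#' @export
next_smooth235 <- function(n) {
  m <- max(1L, as.integer(ceiling(n - 1e-9)))
  repeat {
    r <- m
    for (p in c(2L, 3L, 5L)) while (r %% p == 0L) r <- r %/% p
    if (r == 1L) return(m)
    m <- m + 1L
  }
}

#' Map grid shape for a cell at a resolution bin
#'
#' Per axis: `cell_length * sampling_factor / d_min`, rounded up to the
#' next FFT-friendly (2,3,5-smooth) integer. Sampling factors above 2
#' guarantee the Shannon condition for the reflection sphere.
#'
#' @param cell_lengths length-3 numeric, angstroms.
#' @param bin a [resolution_bin()] row.
#' @return integer length-3 shape.
#' @export
grid_shape_for <- function(cell_lengths, bin) {
  raw <- cell_lengths * bin$sampling_factor / bin$d_min
  vapply(raw, next_smooth235, integer(1))
}

#' Build one dataset example
#'
#' Composes the crystal and reciprocal-space stages: the ground-truth
#' fragment is reoriented, boxed by contact-driven expansion, converted to
#' P21, and its Patterson and density maps synthesised at the bin's
#' resolution limit and grid shape. Each partial structure is the predicted
#' fragment minus an omitted-residue run, every B factor reset to 20.0 A^2,
#' placed in the *same* P21 cell (same screw mate, shape and d_min) so all
#' tensors of the example are aligned.
#'
#' @param fragment ground-truth fragment (Cartesian frame).
#' @param predicted_fragment prediction already aligned to the same frame.
#' @param bin a [resolution_bin()] row.
#' @param seed integer seed driving the P21 multiplier and omission draws.
#' @param J maximum partial structures.
#' @param min_contact,mask_radius crystal-stage parameters.
#' @param mode scattering-factor mode.
#' @param frag_len,n_omit_range passed to [make_partials()] (defaults: the
#'   standard 15-residue fragments with 3-7 omitted residues).
#' @return object of class `dataset_example`: list with `patterson`,
#'   `ground_truth`, `partials` (each `list(map =, record =)`), `bin`,
#'   `cell`, `provenance`.
#' @export
build_example <- function(fragment, predicted_fragment, bin, seed = NULL,
                          J = 3, min_contact = 3.5, mask_radius = 2.2,
                          mode = "cromer-mann", frag_len = 15,
                          n_omit_range = c(3, 7)) {
  fr <- reorient(fragment)
  # the prediction shares the truth's frame: apply the same transform by
  # re-deriving it from the truth's extents
  pred <- apply_same_orientation(fragment, predicted_fragment)
  p1 <- determine_cell(fr, min_contact = min_contact)
  p21 <- to_p21(p1, seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  shape <- grid_shape_for(p21$cell, bin)
  refl <- calc_structure_factors(p21, d_min = bin$d_min, mode = mode)
  gt <- density_map(refl, shape)
  gt$sampling_factor <- bin$sampling_factor
  pat <- patterson_map(refl, shape)
  pat$sampling_factor <- bin$sampling_factor

  partials_src <- make_partials(pred, J = J,
                                seed = if (is.null(seed)) NULL
                                else derive_seed(seed, 2),
                                frag_len = frag_len,
                                n_omit_range = n_omit_range)
  partials <- lapply(partials_src, function(p) {
    pf <- p$fragment
    pf$b <- 20.0
    pcell <- place_in_matching_cell(pf, fragment, p21)
    prefl <- calc_structure_factors(pcell, d_min = bin$d_min, mode = mode)
    pmap <- density_map(prefl, shape, flavor = "template")
    pmap$sampling_factor <- bin$sampling_factor
    list(map = pmap, record = p$record)
  })

  structure(list(patterson = pat, ground_truth = gt, partials = partials,
                 bin = bin, cell = p21,
                 provenance = list(source_id = attr(fragment, "source_id"),
                                   seed = seed)),
            class = "dataset_example")
}

# Re-derive the proper axis permutation chosen for `truth` by reorient()
# and apply the identical transform to `other` (they share one frame).
apply_same_orientation <- function(truth, other) {
  e <- extents(truth)
  ord <- order(e, decreasing = TRUE)
  perm <- c(ord[1], ord[3], ord[2])
  signs <- c(1, 1, 1)
  if (permutation_sign(perm) < 0) signs[3] <- -1
  m <- coords_matrix(other)[, perm, drop = FALSE]
  set_coords(other, sweep(m, 2, signs, "*"))
}

# Place a partial fragment into the exact cell of the ground truth: the
# same Cartesian offset that carried the truth fragment into its P21 cell
# is applied, then the screw mate is generated in that cell.
place_in_matching_cell <- function(partial, truth_fragment, p21) {
  truth_or <- reorient(truth_fragment)
  com <- centre_of_mass(truth_or)
  offset <- p21$cell / 2 - com
  part_or <- apply_same_orientation(truth_fragment, partial)
  placed <- set_coords(part_or,
                       sweep(coords_matrix(part_or), 2, offset, "+"))
  frac <- sweep(coords_matrix(placed), 2, p21$cell, "/")
  mate_frac <- cbind(-frac[, 1], frac[, 2] + 0.5, -frac[, 3]) %% 1
  mate <- set_coords(placed, sweep(mate_frac, 2, p21$cell, "*"))
  placed$copy <- 1L
  mate$copy <- 2L
  unit_cell(dplyr::bind_rows(placed, mate), p21$cell, "P21",
            screw_multiplier = p21$screw_multiplier)
}

#' Normalise a dataset of examples to [-1, 1]
#'
#' Affine per-flavor rescaling x -> 2 (x - min) / (max - min) - 1 with the
#' extremes computed globally over the whole dataset, separately for
#' Patterson and density maps. Partial templates are rescaled with the
#' *density* extremes so templates and targets share a scale.
#'
#' @param examples list of `dataset_example`s.
#' @return list with `examples` (rescaled) and `stats` (per-flavor min/max
#'   tibble, class `normalization_stats`), usable with [denormalize_map()].
#' @export
normalize_dataset <- function(examples) {
  stopifnot(length(examples) >= 1)
  rng_of <- function(maps) range(vapply(maps, function(m) range(m$values),
                                        numeric(2)))
  pat_rng <- rng_of(lapply(examples, function(e) e$patterson))
  den_rng <- rng_of(lapply(examples, function(e) e$ground_truth))
  if (diff(pat_rng) == 0 || diff(den_rng) == 0) {
    rlang::abort("degenerate dataset: a map flavor has max == min")
  }
  stats <- tibble::tibble(flavor = c("patterson", "density"),
                          min = c(pat_rng[1], den_rng[1]),
                          max = c(pat_rng[2], den_rng[2]))
  class(stats) <- c("normalization_stats", class(stats))
  scale_map <- function(m, rng) {
    m$values <- 2 * (m$values - rng[1]) / (rng[2] - rng[1]) - 1
    m
  }
  examples <- lapply(examples, function(ex) {
    ex$patterson <- scale_map(ex$patterson, pat_rng)
    ex$ground_truth <- scale_map(ex$ground_truth, den_rng)
    ex$partials <- lapply(ex$partials, function(p) {
      p$map <- scale_map(p$map, den_rng)   # density extremes by design
      p
    })
    ex
  })
  list(examples = examples, stats = stats)
}

#' Invert dataset normalization for one map
#'
#' @param map a normalised `map_grid`.
#' @param stats the `normalization_stats` from [normalize_dataset()].
#' @param flavor which extremes to invert with (`"patterson"` or
#'   `"density"`; templates use `"density"`).
#' @export
denormalize_map <- function(map, stats, flavor = map$flavor) {
  if (flavor == "template") flavor <- "density"
  row <- stats[stats$flavor == flavor, ]
  map$values <- (map$values + 1) / 2 * (row$max - row$min) + row$min
  map
}

#' Group examples into shape-homogeneous batches
#'
#' Examples are grouped by identical map shape; groups smaller than
#' `min_size` are dropped; larger groups are cut greedily into chunks of
#' `max_size`, rebalancing the last two chunks when the remainder would
#' fall below `min_size`.
#'
#' @param examples list of `dataset_example`s.
#' @param min_size,max_size batch-size bounds (defaults 6 and 11).
#' @return list of batches (each a list of examples).
#' @export
batch_by_shape <- function(examples, min_size = 6, max_size = 11) {
  shapes <- vapply(examples, function(e)
    paste(dim(e$ground_truth$values), collapse = "x"), character(1))
  out <- list()
  for (grp in split(seq_along(examples), shapes)) {
    n <- length(grp)
    if (n < min_size) next
    sizes <- chunk_sizes(n, min_size, max_size)
    start <- 1L
    for (s in sizes) {
      out[[length(out) + 1]] <- examples[grp[start:(start + s - 1L)]]
      start <- start + s
    }
  }
  out
}

# Greedy chunks of max_size; if the remainder is below min_size, move
# examples from the last full chunk to bring it up.
chunk_sizes <- function(n, min_size, max_size) {
  sizes <- rep(max_size, n %/% max_size)
  rem <- n %% max_size
  if (rem > 0) {
    if (rem >= min_size || length(sizes) == 0) {
      sizes <- c(sizes, rem)
    } else {
      need <- min_size - rem
      sizes[length(sizes)] <- sizes[length(sizes)] - need
      sizes <- c(sizes, rem + need)
    }
  }
  sizes[sizes > 0]
}

#' Group fragments into train/test splits by source structure
#'
#' All fragments sharing a `source_id` land in the same split, preventing
#' leakage of near-identical windows between training and evaluation.
#'
#' @param fragments list of fragments.
#' @param test_fraction fraction of source structures assigned to test.
#' @param seed optional integer seed.
#' @return tibble: `index`, `source_id`, `split`.
#' @export
split_by_source <- function(fragments, test_fraction = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  src <- vapply(fragments, function(f) attr(f, "source_id") %||% "?",
                character(1))
  groups <- unique(src)
  test_groups <- sample(groups, size = max(1, round(test_fraction *
                                                      length(groups))))
  tibble::tibble(index = seq_along(fragments), source_id = src,
                 split = ifelse(src %in% test_groups, "test", "train"))
}
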