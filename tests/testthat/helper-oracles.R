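# Independent brute-force oracles and small fixture builders shared by the
# test files. These deliberately re-derive quantities by the slowest,
# most literal route available so they stay independent of the package's
# vectorised implementations.

# exhaustive minimum intermolecular distance: double loop over all atom
# pairs, all symmetry copies and all 27 neighbour-cell translations
brute_min_contact <- function(cell) {
  atoms <- cell$atoms
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  copy <- atoms$copy
  best <- Inf
  for (t1 in -1:1) for (t2 in -1:1) for (t3 in -1:1) {
    shift <- c(t1, t2, t3) * cell$cell
    for (i in seq_len(nrow(xyz))) {
      for (j in seq_len(nrow(xyz))) {
        same_copy <- copy[i] == copy[j]
        if (same_copy && t1 == 0 && t2 == 0 && t3 == 0) next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ] - shift)^2))
        if (d < best) best <- d
      }
    }
  }
  best
}

# direct structure-factor sum for one (h, k, l), at most literal pace
direct_sf <- function(cell, h, k, l, mode = "cromer-mann") {
  frac <- sweep(cbind(cell$atoms$x, cell$atoms$y, cell$atoms$z), 2,
                cell$cell, "/")
  d <- 1 / sqrt(h^2 / cell$cell[1]^2 + k^2 / cell$cell[2]^2 +
                  l^2 / cell$cell[3]^2)
  s <- 1 / d
  f <- 0 + 0i
  for (j in seq_len(nrow(frac))) {
    fj <- scattering_factor(cell$atoms$element[j], s, mode)
    dw <- exp(-cell$atoms$b[j] * s^2 / 4)
    f <- f + fj * dw * exp(2i * pi * (h * frac[j, 1] + k * frac[j, 2] +
                                        l * frac[j, 3]))
  }
  f
}

# direct real-space synthesis of Eq.-style density: triple loop over grid
# points, explicit sum over stored reflections and their Friedel mates
direct_density <- function(refl, shape) {
  cell <- attr(refl, "cell")
  vol <- prod(cell)
  out <- array(0, dim = shape)
  for (i1 in seq_len(shape[1])) for (i2 in seq_len(shape[2])) {
    for (i3 in seq_len(shape[3])) {
      x <- (i1 - 1) / shape[1]; y <- (i2 - 1) / shape[2]
      z <- (i3 - 1) / shape[3]
      acc <- sum(refl$f * exp(-2i * pi * (refl$h * x + refl$k * y +
                                            refl$l * z)))
      acc <- acc + sum(Conj(refl$f) * exp(-2i * pi * (-refl$h * x -
                                                        refl$k * y -
                                                        refl$l * z)))
      out[i1, i2, i3] <- Re(acc) / vol
    }
  }
  out
}

# tiny hand-built fragment: explicit atoms, no randomness
tiny_fragment <- function(coords, elements = NULL, b = 15) {
  n <- nrow(coords)
  if (is.null(elements)) elements <- rep("C", n)
  new_fragment(tibble::tibble(
    resid = 1L, resname = "GLY",
    atom = paste0("C", seq_len(n)), element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    b = b, occ = 1.0), source_id = "tiny")
}

# quick small P21 cell from a seeded fixture fragment
quick_p21 <- function(seed, n_residues = 3) {
  fr <- make_fragment(fixture_spec(n_residues = n_residues), seed = seed)
  to_p21(determine_cell(reorient(fr)), seed = seed + 1000)
}

# same exhaustive 27-translation image search, with the inner atom loop
# vectorised; used by the larger Monte-Carlo batches
brute_min_contact_fast <- function(cell) {
  atoms <- cell$atoms
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  copy <- atoms$copy
  best <- Inf
  for (t1 in -1:1) for (t2 in -1:1) for (t3 in -1:1) {
    shift <- c(t1, t2, t3) * cell$cell
    at_origin <- t1 == 0 && t2 == 0 && t3 == 0
    for (i in seq_len(nrow(xyz))) {
      d2 <- rowSums(sweep(xyz, 2, xyz[i, ] + shift, "-")^2)
      same <- copy == copy[i]
      if (at_origin) d2[same] <- Inf
      best <- min(best, min(d2))
    }
  }
  sqrt(best)
}
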