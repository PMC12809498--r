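test_that("reorientation orders extents and preserves geometry exactly", {
  # extents (10, 20, 15) must reorder to (20, 10, 15)
  set.seed(2)
  m <- cbind(runif(40, 0, 10), runif(40, 0, 20), runif(40, 0, 15))
  m[1, ] <- c(0, 0, 0); m[2, ] <- c(10, 20, 15)   # pin the extents
  fr <- tiny_fragment(m)
  out <- reorient(fr)
  expect_equal(unname(extents(out)), c(20, 10, 15))

  # already-ordered input is untouched
  m2 <- m[, c(2, 1, 3)]
  fr2 <- tiny_fragment(m2)
  expect_equal(coords_matrix(reorient(fr2)), coords_matrix(fr2))

  # pairwise distances and chirality preserved for random fragments
  for (s in 1:10) {
    fr <- make_fragment(fixture_spec(), seed = s)
    out <- reorient(fr)
    expect_lt(max(abs(dist(coords_matrix(fr)) - dist(coords_matrix(out)))),
              1e-9)
    # signed tetrahedron volume of 4 atoms flips under improper transforms
    vol_of <- function(x) det(rbind(x[2, ] - x[1, ], x[3, ] - x[1, ],
                                    x[4, ] - x[1, ]))
    expect_equal(sign(vol_of(coords_matrix(out)[1:4, ])),
                 sign(vol_of(coords_matrix(fr)[1:4, ])))
  }

  collinear <- tiny_fragment(cbind(1:5, 1:5, 1:5))
  expect_error(reorient(collinear), "degenerate")
})

test_that("min_contact matches hand-computable cases and the brute oracle", {
  one <- tiny_fragment(matrix(c(1, 1, 1), nrow = 1))
  expect_equal(min_contact(unit_cell(one, c(5, 5, 5))), 5)
  centred <- tiny_fragment(matrix(c(4, 4, 4), nrow = 1))
  expect_equal(min_contact(unit_cell(centred, c(8, 8, 8))), 8)

  for (s in 1:5) {
    cell <- quick_p21(s)
    expect_equal(min_contact(cell), brute_min_contact(cell), tolerance = 1e-9)
  }
})

test_that("cell determination enforces the contact threshold", {
  one <- tiny_fragment(matrix(0, nrow = 1, ncol = 3))
  cell <- determine_cell(one)
  expect_true(all(cell$cell >= 3.5))

  two <- tiny_fragment(rbind(c(0, 0, 0), c(4, 0, 0)))
  cell2 <- determine_cell(two)
  expect_gte(brute_min_contact(cell2), 3.5)

  for (s in 1:15) {
    fr <- reorient(make_fragment(fixture_spec(), seed = s))
    cell <- determine_cell(fr)
    expect_gte(brute_min_contact(cell), 3.5 - 1e-9)
  }
  expect_error(determine_cell(one, min_contact = -1), "positive")
})

test_that("P21 conversion applies the screw operator and stated expansions", {
  fr <- reorient(make_fragment(fixture_spec(), seed = 4))
  p1 <- determine_cell(fr)
  p21 <- to_p21(p1, seed = 99)

  expect_equal(nrow(p21$atoms), 2 * nrow(p1$atoms))
  expect_equal(p21$cell[1], p1$cell[1] + 1)
  expect_equal(p21$cell[3], p1$cell[3] + 1)
  ratio <- p21$cell[2] / (p1$cell[2] + 1)
  expect_true(ratio >= 1.7 && ratio <= 1.95)
  expect_equal(ratio, p21$screw_multiplier)

  # screw relation exact in fractional coordinates (mod 1)
  frac <- frac_coords(p21)
  n <- nrow(frac) / 2
  orig <- frac[1:n, ]; mate <- frac[n + 1:n, ]
  wrap <- function(x) x - round(x)
  expect_lt(max(abs(wrap(mate[, 1] + orig[, 1]))), 1e-9)
  expect_lt(max(abs(wrap(mate[, 2] - orig[, 2] - 0.5))), 1e-9)
  expect_lt(max(abs(wrap(mate[, 3] + orig[, 3]))), 1e-9)

  # deterministic under seed; re-conversion is rejected
  expect_identical(to_p21(p1, seed = 99)$cell, p21$cell)
  expect_error(to_p21(p21, seed = 1), "P1")

  # multiplier stays inside the sampled range across seeds
  ratios <- vapply(1:200, function(s) {
    out <- to_p21(p1, seed = s)
    out$cell[2] / (p1$cell[2] + 1)
  }, numeric(1))
  expect_true(all(ratios >= 1.7 & ratios <= 1.95))
})

test_that("solvent fraction agrees with a brute periodic scan and is monotone", {
  one <- tiny_fragment(matrix(c(2, 2, 2), nrow = 1))
  cell <- unit_cell(one, c(10, 10, 10))
  shape <- c(8, 8, 8)
  # brute force: distance from every voxel to the atom under minimum image
  cnt <- 0
  for (i in 0:7) for (j in 0:7) for (k in 0:7) {
    dx <- abs(c(i, j, k) / 8 * 10 - c(2, 2, 2))
    dx <- pmin(dx, 10 - dx)
    if (sqrt(sum(dx^2)) > 2.2) cnt <- cnt + 1
  }
  expect_equal(solvent_fraction(cell, shape), cnt / 512)

  # adding atoms can only reduce the solvent fraction
  fr2 <- tiny_fragment(rbind(c(2, 2, 2), c(7, 7, 7)))
  cell2 <- unit_cell(fr2, c(10, 10, 10))
  expect_lte(solvent_fraction(cell2, shape), solvent_fraction(cell, shape))
})
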