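test_that("synthetic fragments have standard chemistry and ideal geometry", {
  fr <- make_fragment(fixture_spec(), seed = 1)
  expect_equal(n_residues(fr), 15)
  expect_true(all(fr$resname %in% xtalfrag:::STANDARD_RESIDUES))
  expect_false(any(fr$element == "H"))
  expect_true(all(fr$occ == 1.0))
  expect_true(all(fr$b >= 10 & fr$b <= 40))

  # backbone bond-length audit against ideal values
  ideal <- xtalfrag:::IDEAL_GEOM
  get_atom <- function(rid, name) {
    row <- fr[fr$resid == rid & fr$atom == name, ]
    c(row$x, row$y, row$z)
  }
  for (r in 1:15) {
    expect_lt(abs(sqrt(sum((get_atom(r, "N") - get_atom(r, "CA"))^2)) -
                    ideal$n_ca), 0.05)
    expect_lt(abs(sqrt(sum((get_atom(r, "CA") - get_atom(r, "C"))^2)) -
                    ideal$ca_c), 0.05)
    if (r < 15) {
      expect_lt(abs(sqrt(sum((get_atom(r, "C") - get_atom(r + 1, "N"))^2)) -
                      ideal$c_n), 0.05)
    }
  }
})

test_that("fragment generation is deterministic under a seed", {
  a <- make_fragment(fixture_spec(), seed = 42)
  b <- make_fragment(fixture_spec(), seed = 42)
  expect_identical(coords_matrix(a), coords_matrix(b))
  expect_identical(a$b, b$b)
})

test_that("predictions hit the target C-alpha RMSD and carry B = 20", {
  fr <- make_fragment(fixture_spec(), seed = 3)

  same <- make_prediction(fr, fixture_spec(target_rmsd = 0), seed = 1)
  expect_equal(coords_matrix(same), coords_matrix(fr))
  expect_true(all(same$b == 20.0))

  spec1 <- fixture_spec(target_rmsd = 1.0)
  rmsds <- vapply(1:50, function(s) {
    pred <- make_prediction(fr, spec1, seed = s)
    ca <- fr$atom == "CA"
    sqrt(mean(rowSums((coords_matrix(pred)[ca, ] -
                         coords_matrix(fr)[ca, ])^2)))
  }, numeric(1))
  expect_true(all(rmsds >= 0.75 & rmsds <= 1.25))
  expect_true(all(make_prediction(fr, spec1, seed = 9)$b == 20.0))
})

test_that("fixtures pass cleanup unchanged", {
  fr <- make_fragment(fixture_spec(), seed = 7)
  cleaned <- clean_fragment(fr)
  expect_false(is.null(cleaned))
  expect_equal(nrow(cleaned), nrow(fr))
  expect_equal(coords_matrix(cleaned), coords_matrix(fr))
})

test_that("atom-table validation rejects broken input", {
  fr <- make_fragment(fixture_spec(n_residues = 2), seed = 1)
  bad_b <- fr; bad_b$b[1] <- -1
  expect_error(new_fragment(bad_b), "negative B")
  bad_occ <- fr; bad_occ$occ[2] <- 0.5
  expect_error(new_fragment(bad_occ), "occupanc")
  bad_el <- fr; bad_el$element[1] <- "SE"
  expect_error(new_fragment(bad_el), "unsupported element")
  gap <- fr; gap$resid[gap$resid == 2] <- 5L
  expect_error(new_fragment(gap), "contiguous")
})

test_that("derived child seeds stay within 32-bit range and differ", {
  seeds <- vapply(0:200, function(i) derive_seed(1234, i), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_gt(length(unique(seeds)), 195)
})
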