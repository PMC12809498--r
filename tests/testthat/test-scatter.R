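test_that("scattering factors behave like the tabulated atoms", {
  expect_equal(scattering_factor("C", 0.3, "constant-z"), 6)
  expect_equal(scattering_factor("S", 0, "cromer-mann"), 16, tolerance = 0.5 / 16)
  s_grid <- seq(0, 0.6, by = 0.01)
  for (el in c("C", "N", "O", "S")) {
    f <- scattering_factor(el, s_grid, "cromer-mann")
    expect_true(all(diff(f) < 0))
  }
  expect_error(scattering_factor("Fe", 0.1), "unknown element")
})

test_that("structure factors reproduce closed-form single-atom cases", {
  at_origin <- tiny_fragment(matrix(0, 1, 3), b = 0)
  cell <- unit_cell(at_origin, c(6, 6, 6))
  refl <- calc_structure_factors(cell, d_min = 2.5, mode = "constant-z")
  expect_true(all(abs(refl$f - 6) < 1e-10))

  at_half <- tiny_fragment(matrix(c(3, 0, 0), 1, 3), b = 0)
  cell2 <- unit_cell(at_half, c(6, 6, 6))
  refl2 <- calc_structure_factors(cell2, d_min = 2.5, mode = "constant-z")
  f100 <- refl2$f[refl2$h == 1 & refl2$k == 0 & refl2$l == 0]
  expect_equal(f100, complex(real = -6), tolerance = 1e-10)
})

test_that("vectorised structure factors match the direct per-atom sum", {
  cell <- quick_p21(21)
  refl <- calc_structure_factors(cell, d_min = 3.0)
  pick <- seq(1, nrow(refl), length.out = 25)
  for (i in as.integer(pick)) {
    expect_equal(refl$f[i], direct_sf(cell, refl$h[i], refl$k[i], refl$l[i]),
                 tolerance = 1e-8)
  }
  # Friedel mates are conjugates, by the independent direct sum
  for (i in as.integer(seq(1, nrow(refl), length.out = 8))) {
    expect_equal(direct_sf(cell, -refl$h[i], -refl$k[i], -refl$l[i]),
                 Conj(refl$f[i]), tolerance = 1e-8)
  }
})

test_that("the 2_1 screw forces odd 0k0 reflections to vanish", {
  for (s in 1:5) {
    cell <- quick_p21(30 + s)
    refl <- calc_structure_factors(cell, d_min = 2.5)
    absent <- refl[refl$h == 0 & refl$l == 0 & refl$k %% 2 == 1, ]
    if (nrow(absent) > 0) expect_lt(max(Mod(absent$f)), 1e-8)
    present <- refl[refl$h == 0 & refl$l == 0 & refl$k %% 2 == 0, ]
    if (nrow(present) > 0) expect_gt(max(Mod(present$f)), 1e-3)
  }
})

test_that("FFT density equals the direct triple sum and is mean-zero", {
  cell <- quick_p21(40, n_residues = 2)
  refl <- calc_structure_factors(cell, d_min = 4.0)
  shape <- c(8, 8, 8)
  dm <- density_map(refl, shape)
  expect_lt(max(abs(dm$values - direct_density(refl, shape))) /
              max(abs(dm$values)), 1e-8)
  expect_lt(abs(mean(dm$values)), 1e-10)
})

test_that("a single B-damped atom peaks at its own grid node", {
  pos <- c(2.1, 3.9, 5.2)
  fr <- tiny_fragment(matrix(pos, 1, 3), b = 20)
  cell <- unit_cell(fr, c(8, 8, 8))
  refl <- calc_structure_factors(cell, d_min = 2.0)
  dm <- density_map(refl, c(16, 16, 16))
  peak <- which(dm$values == max(dm$values), arr.ind = TRUE)[1, ]
  nearest <- round(pos / 8 * 16) + 1
  expect_equal(unname(peak), unname(nearest))
})

test_that("grids too coarse for the reflection set are rejected", {
  cell <- quick_p21(41, n_residues = 2)
  refl <- calc_structure_factors(cell, d_min = 3.0)
  expect_error(density_map(refl, c(4, 4, 4)), "too coarse")
})

test_that("Patterson maps are centrosymmetric with a dominant origin peak", {
  for (s in 1:10) {
    cell <- quick_p21(50 + s, n_residues = 2)
    refl <- calc_structure_factors(cell, d_min = 3.0)
    shape <- vapply(2 * floor(cell$cell / 3.0) + 3, next_smooth235, integer(1))
    pm <- patterson_map(refl, shape)
    v <- pm$values
    ridx <- function(m) c(1L, if (m > 1) m:2L)
    flipped <- v[ridx(shape[1]), ridx(shape[2]), ridx(shape[3])]
    expect_lt(max(abs(v - flipped)), 1e-10 * max(abs(v)))
    expect_equal(which.max(v), 1L)
  }
})

test_that("two equal atoms give the textbook interatomic Patterson peaks", {
  fr <- tiny_fragment(rbind(c(2, 2, 2), c(5, 2, 2)), b = 0)
  cell <- unit_cell(fr, c(12, 9, 9))
  refl <- calc_structure_factors(cell, d_min = 1.5, mode = "constant-z")
  pm <- patterson_map(refl, c(24, 16, 16))
  origin <- pm$values[1, 1, 1]
  # vector t = (3, 0, 0) A -> grid offset 24 * 3/12 = 6
  peak <- pm$values[7, 1, 1]
  expect_equal(peak / origin, 0.5, tolerance = 0.05)
})

test_that("Patterson ignores phases and atom translations", {
  cell <- quick_p21(61, n_residues = 2)
  refl <- calc_structure_factors(cell, d_min = 3.0)
  shape <- vapply(2 * floor(cell$cell / 3.0) + 3, next_smooth235, integer(1))
  pm <- patterson_map(refl, shape)

  # scramble every phase: the squared-amplitude synthesis cannot see it
  set.seed(8)
  scrambled <- refl
  scrambled$f <- complex(modulus = Mod(refl$f),
                         argument = runif(nrow(refl), -pi, pi))
  pm2 <- patterson_map(scrambled, shape)
  expect_lt(max(abs(pm$values - pm2$values)), 1e-8 * max(abs(pm$values)))

  # translate the whole contents by a lattice fraction: Patterson unchanged
  shifted <- cell
  shifted$atoms$x <- shifted$atoms$x + cell$cell[1] / 4
  refl3 <- calc_structure_factors(shifted, d_min = 3.0)
  pm3 <- patterson_map(refl3, shape)
  expect_lt(max(abs(pm$values - pm3$values)), 1e-6 * max(abs(pm$values)))
})

test_that("autocorrelation route reproduces the squared-amplitude route", {
  cell <- quick_p21(70, n_residues = 2)
  refl <- calc_structure_factors(cell, d_min = 3.0)
  shape <- vapply(2 * floor(cell$cell / 3.0) + 3, next_smooth235, integer(1))
  e <- density_map(refl, shape)
  p_direct <- patterson_map(refl, shape)
  p_auto <- patterson_via_autocorrelation(e)
  expect_lt(max(abs(p_direct$values - p_auto$values)) /
              max(abs(p_direct$values)), 1e-6)

  # degenerate inputs
  zero <- map_grid(array(0, dim = c(4, 4, 4)), c(5, 5, 5), "density")
  expect_true(all(patterson_via_autocorrelation(zero)$values == 0))
  delta <- map_grid(array(c(1, rep(0, 63)), dim = c(4, 4, 4)), c(5, 5, 5),
                    "density")
  pd <- patterson_via_autocorrelation(delta)
  expect_equal(which.max(abs(pd$values)), 1L)
  expect_lt(max(abs(pd$values[-1])), 1e-12)
})

test_that("map-derived structure factors invert the synthesis", {
  cell <- quick_p21(71, n_residues = 2)
  refl <- calc_structure_factors(cell, d_min = 3.0)
  shape <- vapply(2 * floor(cell$cell / 3.0) + 3, next_smooth235, integer(1))
  e <- density_map(refl, shape)
  back <- map_to_structure_factors(e, refl)
  expect_lt(max(Mod(back$f - refl$f)), 1e-8 * max(Mod(refl$f)))
  expect_error(map_to_structure_factors(
    map_grid(array(0, c(3, 3, 3)), cell$cell, "density"), refl),
    "too coarse")
})
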