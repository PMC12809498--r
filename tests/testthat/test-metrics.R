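test_that("map correlation honours the textbook identities", {
  set.seed(1)
  e <- map_grid(array(rnorm(4^3), dim = c(4, 4, 4)), c(8, 8, 8), "density")
  neg <- e; neg$values <- -e$values
  shifted <- e; shifted$values <- e$values + 3.7
  expect_equal(pearson_cc(e, e), 1.0)
  expect_equal(pearson_cc(e, neg), -1.0)
  expect_equal(pearson_cc(e, shifted), 1.0)

  mask <- array(FALSE, dim = c(4, 4, 4)); mask[1:2, 1, 1] <- TRUE
  expect_equal(pearson_cc(e, e, mask), 1.0)
  expect_error(pearson_cc(e, e, mask & FALSE), "at least 2")

  flat <- e; flat$values[] <- 2
  expect_error(pearson_cc(e, flat), "zero variance")
})

test_that("the in-model mask selects voxels near atoms, periodically", {
  fr <- tiny_fragment(matrix(c(0.1, 0.1, 0.1), 1, 3))
  cell <- unit_cell(fr, c(10, 10, 10))
  mask <- in_model_mask(cell, c(10, 10, 10), radius = 2.0)
  expect_true(mask[1, 1, 1])
  expect_true(mask[10, 10, 10])    # wraps around the cell edge
  expect_false(mask[5, 5, 5])
})

test_that("phase errors follow known constant-offset cases", {
  cell <- quick_p21(81, n_residues = 2)
  refl <- calc_structure_factors(cell, d_min = 3.0)

  same <- phase_error(refl, refl)
  expect_equal(attr(same, "mean_dphi"), 0)
  expect_equal(attr(same, "mean_cos"), 1)

  rot <- refl
  rot$f <- refl$f * exp(1i * 30 * pi / 180)
  pc <- phase_error(rot, refl)
  expect_equal(attr(pc, "mean_dphi"), 30, tolerance = 1e-9)
  expect_equal(attr(pc, "mean_cos"), cos(30 * pi / 180), tolerance = 1e-9)
  g <- glance(pc)
  expect_equal(g$phase_error_unweighted, 30, tolerance = 1e-9)
  expect_equal(nrow(tidy(pc)), nrow(refl))

  other <- refl[-1, ]
  expect_error(phase_error(other, refl), "differ")
})

test_that("uniform random phase differences average 90 degrees", {
  set.seed(4)
  n <- 1e4
  base <- reflection_set(tibble::tibble(
    h = rep(1:100, each = 100), k = rep(1:100, times = 100), l = 1L,
    f = complex(modulus = 1, argument = runif(n, -pi, pi)),
    d = rep(3, n)), cell = c(300, 300, 300), d_min = 2)
  rand <- base
  rand$f <- complex(modulus = 1, argument = runif(n, -pi, pi))
  pc <- phase_error(rand, base)
  expect_equal(attr(pc, "mean_dphi"), 90, tolerance = 2 / 90)
})

test_that("FOM weighting changes the aggregate the way the formula says", {
  cell <- quick_p21(82, n_residues = 2)
  refl <- calc_structure_factors(cell, d_min = 3.0)
  rot <- refl
  rot$f <- refl$f * exp(1i * 60 * pi / 180)
  m <- runif(nrow(refl))
  pc <- phase_error(rot, refl, foms = m)
  expect_equal(attr(pc, "mean_dphi_weighted"), sum(m * 60) / sum(m),
               tolerance = 1e-9)
})

test_that("E values are unit-power per shell and scale-free", {
  cell <- quick_p21(83)
  refl <- calc_structure_factors(cell, d_min = 2.5)
  ev <- normalized_amplitudes(refl, n_shells = 8)
  power <- tapply(ev$e^2, ev$shell, mean)
  expect_true(all(abs(power - 1) < 1e-10))

  scaled <- refl
  scaled$f <- refl$f * 10
  ev10 <- normalized_amplitudes(scaled, n_shells = 8)
  expect_equal(ev$e, ev10$e, tolerance = 1e-12)

  const <- refl
  const$f <- complex(modulus = 1, argument = Arg(refl$f))
  evc <- normalized_amplitudes(const, n_shells = 8)
  expect_true(all(abs(evc$e - 1) < 1e-12))
})

test_that("sigma-A separates perfect, decent and unrelated models", {
  cell <- quick_p21(84)
  truth <- calc_structure_factors(cell, d_min = 2.5)
  e_t <- normalized_amplitudes(truth, n_shells = 5)

  perfect <- estimate_sigma_a(e_t, e_t)
  expect_true(all(perfect$sigma_a >= 0.95))
  expect_true(all(perfect$sigma_a < 1))

  # unrelated model: synthetic acentric-like E values, independent draws
  set.seed(6)
  n <- 1e4
  fake_set <- function(e_vals) {
    tb <- tibble::tibble(h = seq_len(n), k = 1L, l = 1L, d = rep(2.5, n),
                         amp = e_vals, e = NA_real_,
                         shell = rep(1:5, length.out = n))
    for (sh in 1:5) {
      idx <- tb$shell == sh
      tb$e[idx] <- tb$amp[idx] / sqrt(mean(tb$amp[idx]^2))
    }
    tb
  }
  eo <- fake_set(sqrt(stats::rexp(n)))
  ec <- fake_set(sqrt(stats::rexp(n)))
  null_fit <- estimate_sigma_a(eo, ec)
  expect_true(all(null_fit$sigma_a < 0.2))
  expect_true(all(null_fit$sigma_a >= 0))
})

test_that("figures of merit rise monotonically from 0 towards 1", {
  expect_equal(fom(0, 1, 0.5, centric = FALSE), 0)
  expect_equal(fom(0, 1, 0.5, centric = TRUE), 0)

  x_grid <- seq(0.1, 8, by = 0.1)
  m_ac <- fom(x_grid, rep(1, length(x_grid)), rep(0.5, length(x_grid)),
              centric = rep(FALSE, length(x_grid)))
  m_c <- fom(x_grid, rep(1, length(x_grid)), rep(0.5, length(x_grid)),
             centric = rep(TRUE, length(x_grid)))
  expect_true(all(diff(m_ac) > 0))
  expect_true(all(diff(m_c) > 0))
  big <- fom(50, 50, 0.9, centric = FALSE)
  expect_gt(big, 0.99)
  expect_lte(big, 1)
  expect_warning(fom(1, 1, 1, centric = FALSE), "clamped")
})

test_that("sigma-A weighted maps recover truth from a perfect partial model", {
  cell <- quick_p21(85)
  truth <- calc_structure_factors(cell, d_min = 2.8)
  shape <- grid_shape_for(cell$cell,
                          tibble::tibble(d_min = 2.8, sampling_factor = 2.3))
  truth_map <- density_map(truth, shape)

  sp <- sigmaa_pipeline(truth, truth, shape)
  expect_gte(pearson_cc(sp$map, truth_map), 0.99)
  expect_true(all(sp$foms >= 0 & sp$foms <= 1))

  # zero figures of merit null the synthesis
  zero <- sigmaa_weighted_map(Mod(truth$f), truth,
                              d_scale = rep(0, nrow(truth)),
                              foms = rep(0, nrow(truth)),
                              centric = truth$k == 0L, shape = shape)
  expect_true(all(zero$values == 0))
})
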