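toy_cfg <- toy_model_config()

test_that("the forward pass honours the shape contract", {
  params <- init_params(toy_cfg, seed = 1)
  set.seed(2)
  for (shape in list(c(8, 8, 8), c(10, 12, 9))) {    # second is non-divisible
    pat <- array(rnorm(prod(shape)), dim = shape)
    tmpl <- array(rnorm(prod(shape)), dim = shape)
    out <- model_forward(pat, tmpl, params, toy_cfg)
    expect_identical(dim(out$values), as.integer(shape))
    expect_true(all(is.finite(out$values)))
  }
  expect_error(model_forward(array(0, c(8, 8, 8)), array(0, c(8, 8, 9)),
                             params, toy_cfg),
               "shapes differ")
})

test_that("the composite loss reduces to its closed-form corners", {
  set.seed(3)
  truth <- map_grid(array(rnorm(6^3), dim = c(6, 6, 6)), c(9, 9, 9),
                    "density")
  expect_equal(model_loss(truth, truth, pc_weight = 1), -1)
  expect_equal(model_loss(truth, truth, pc_weight = 0), 0)

  flat <- truth; flat$values[] <- 0
  expect_warning(l <- model_loss(truth, flat, pc_weight = 1),
                 "zero-variance")
  expect_equal(l, mean(truth$values^2))

  # with pc_weight = 0 the loss is exactly the mean squared error
  other <- truth; other$values <- truth$values + 0.5
  expect_equal(model_loss(other, truth, pc_weight = 0), 0.25,
               tolerance = 1e-12)
})

test_that("the one-cycle schedule hits its three endpoints exactly", {
  cfg <- train_config(steps = 200)
  s_peak <- max(2, ceiling(0.3 * 200))
  expect_equal(one_cycle_lr(1, cfg), cfg$lr_initial, tolerance = 1e-9)
  expect_equal(one_cycle_lr(s_peak, cfg), cfg$lr_max, tolerance = 1e-9)
  expect_equal(one_cycle_lr(200, cfg), cfg$lr_final, tolerance = 1e-9)
  lrs <- vapply(1:200, one_cycle_lr, numeric(1), cfg = cfg)
  expect_equal(which.max(lrs), s_peak)
})

test_that("Nystrom attention approaches exact attention as landmarks grow", {
  set.seed(5)
  n <- 32; d <- 8
  q <- matrix(rnorm(n * d), n); k <- matrix(rnorm(n * d), n)
  v <- matrix(rnorm(n * d), n)
  logits <- (q %*% t(k)) / sqrt(d)
  logits <- logits - apply(logits, 1, max)
  w <- exp(logits)
  exact <- (w / rowSums(w)) %*% v

  err_at <- function(m) {
    norm(nystrom_attention(q, k, v, landmarks = m, iters = 6) - exact,
         "F") / norm(exact, "F")
  }
  expect_equal(err_at(32), 0, tolerance = 1e-12)   # falls back to exact
  expect_lt(err_at(16), err_at(4))
})

test_that("training is deterministic under a fixed seed", {
  set.seed(6)
  shape <- c(6, 6, 6)
  recs <- lapply(1:2, function(i) {
    list(patterson = array(rnorm(prod(shape)), dim = shape),
         partial = array(rnorm(prod(shape)), dim = shape),
         truth = array(rnorm(prod(shape)), dim = shape))
  })
  cfg <- toy_model_config(n_layers = 2, downsample_after = 1,
                          upsample_after = 2, embed_dim = 24, n_heads = 2,
                          head_dim = 8, mlp_dim = 32, conv_channels = 4)
  tc <- train_config(steps = 5, seed = 9)
  f1 <- train_toy(recs, cfg, tc, batch_size = 2)
  f2 <- train_toy(recs, cfg, tc, batch_size = 2)
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-5)
  expect_equal(nrow(f1$history), 5)
  expect_equal(f1$history$lr, vapply(1:5, one_cycle_lr, numeric(1), cfg = tc))

  g <- glance(f1)
  expect_gt(g$n_parameters, 0)
  expect_equal(g$steps, 5)
  expect_equal(nrow(tidy(f1)), 5)
  expect_error(train_toy(list(), cfg, tc), "empty")
})

test_that("the scale-equivariant stem flag changes only the stem", {
  cfg_se <- toy_model_config(scale_equivariant = TRUE)
  params <- init_params(cfg_se, seed = 2)
  set.seed(7)
  pat <- array(rnorm(8^3), dim = c(8, 8, 8))
  out <- model_forward(pat, pat, params, cfg_se)
  expect_identical(dim(out$values), c(8L, 8L, 8L))
  expect_true(all(is.finite(out$values)))
})
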