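# finite-difference validation of the reverse-mode tape; the oracle is the
# symmetric difference quotient of the scalarised loss sum(f(x) * w)
fd_check <- function(build, x0, tol = 1e-5) {
  probe <- build(xtalfrag:::ad_leaf(x0))
  w_mask <- stats::rnorm(length(probe$val))
  scalarise <- function(node) {
    xtalfrag:::ad_sum(xtalfrag:::ad_mul(node, xtalfrag:::ad_leaf(
      array(w_mask, dim = dim(node$val) %||% length(node$val)))))
  }
  leaf <- xtalfrag:::ad_leaf(x0)
  loss <- scalarise(build(leaf))
  xtalfrag:::ad_backward(loss)
  g_ad <- leaf$grad
  eps <- 1e-6
  g_fd <- array(0, dim = dim(x0) %||% length(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    fp <- sum(xtalfrag:::ad_value(build(xtalfrag:::ad_leaf(xp))) * w_mask)
    fm <- sum(xtalfrag:::ad_value(build(xtalfrag:::ad_leaf(xm))) * w_mask)
    g_fd[i] <- (fp - fm) / (2 * eps)
  }
  expect_lt(max(abs(g_ad - g_fd)), tol * max(1, max(abs(g_fd))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("every differentiable op matches finite differences", {
  set.seed(10)
  x <- matrix(rnorm(12), 4, 3)
  b_mat <- matrix(rnorm(6), 3, 2)
  idx_dup <- matrix(sample(12, 20, replace = TRUE), 5, 4)

  gamma0 <- rnorm(3) + 1
  beta0 <- rnorm(3)
  bias0 <- rnorm(3)
  other0 <- matrix(rnorm(12), 4, 3)

  fd_check(function(n) xtalfrag:::ad_matmul(n, xtalfrag:::ad_leaf(b_mat)), x)
  fd_check(function(n) xtalfrag:::ad_add(n, xtalfrag:::ad_leaf(x * 2)), x)
  fd_check(function(n) xtalfrag:::ad_mul(n, xtalfrag:::ad_leaf(x + 1)), x)
  fd_check(function(n) xtalfrag:::ad_gather(n, idx_dup), x)
  fd_check(function(n) xtalfrag:::ad_softmax_rows(n), x)
  fd_check(function(n) xtalfrag:::ad_gelu(n), x)
  fd_check(function(n) xtalfrag:::ad_transpose(n), x)
  fd_check(function(n)
    xtalfrag:::ad_layernorm_rows(n, xtalfrag:::ad_leaf(gamma0),
                                 xtalfrag:::ad_leaf(beta0)), x,
    tol = 1e-4)
  fd_check(function(n)
    xtalfrag:::ad_add_bias(n, xtalfrag:::ad_leaf(bias0)), x)
  fd_check(function(n)
    xtalfrag:::ad_pearson(n, xtalfrag:::ad_leaf(other0)),
    x, tol = 1e-4)
})

test_that("gather with duplicated indices accumulates gradients", {
  x <- xtalfrag:::ad_leaf(c(1, 2, 3))
  y <- xtalfrag:::ad_gather(x, c(1L, 1L, 2L), 3)
  s <- xtalfrag:::ad_sum(y)
  xtalfrag:::ad_backward(s)
  expect_equal(as.vector(x$grad), c(2, 1, 0))
})

test_that("the recording tape gives the same gradients as the DFS sweep", {
  set.seed(11)
  x0 <- matrix(rnorm(20), 5, 4)
  w0 <- matrix(rnorm(16), 4, 4)
  run <- function(record) {
    if (record) xtalfrag:::ad_tape_start()
    x <- xtalfrag:::ad_leaf(x0)
    w <- xtalfrag:::ad_leaf(w0)
    h <- xtalfrag:::ad_gelu(xtalfrag:::ad_matmul(x, w))
    loss <- xtalfrag:::ad_mean(xtalfrag:::ad_mul(h, h))
    xtalfrag:::ad_backward(loss)
    if (record) xtalfrag:::ad_tape_stop()
    list(w = w$grad, x = x$grad, val = xtalfrag:::ad_value(loss))
  }
  a <- run(FALSE)
  b <- run(TRUE)
  expect_equal(a$val, b$val)
  expect_equal(a$w, b$w, tolerance = 1e-12)
  expect_equal(a$x, b$x, tolerance = 1e-12)
})
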