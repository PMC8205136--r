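# Gradient and shape checks of the CNN engine primitives, against central
# finite differences on tiny inputs.

geom44 <- greyunet:::nn_geometry(1, 4, 4)

fd_check <- function(fwd, bwd, X, n_out_cols, tol = 1e-6) {
  set.seed(99)
  res <- fwd(X)
  dY <- matrix(rnorm(length(res$out)), ncol = n_out_cols)
  dX <- bwd(dY, res)
  for (i in sample(length(X), min(6, length(X)))) {
    f <- function(v) { X2 <- X; X2[i] <- v; sum(fwd(X2)$out * dY) }
    expect_equal(dX[i], num_deriv(f, X[i]), tolerance = tol)
  }
}

test_that("3x3 same-padding convolution: forward matches naive loop, backward matches finite differences", {
  set.seed(21)
  pars <- greyunet:::conv3_init(2, 3)
  X <- matrix(rnorm(16 * 2), 16, 2)
  out <- greyunet:::conv3_forward(X, pars, geom44)$out
  expect_equal(dim(out), c(16L, 3L))

  # naive oracle: explicit loop over output pixels and kernel offsets
  Warr <- array(pars$W, c(9, 2, 3))  # rows of W are offset-major, channel within
  img <- array(X, c(4, 4, 2))
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  naive <- array(0, c(4, 4, 3))
  for (y in 1:4) for (x in 1:4) for (co in 1:3) {
    acc <- pars$b[co]
    for (o in 1:9) for (ci in 1:2) {
      yy <- y + offs$dy[o]; xx <- x + offs$dx[o]
      if (yy >= 1 && yy <= 4 && xx >= 1 && xx <= 4)
        acc <- acc + img[yy, xx, ci] * pars$W[(o - 1) * 2 + ci, co]
    }
    naive[y, x, co] <- acc
  }
  expect_equal(matrix(naive, 16, 3), out)

  fd_check(function(X) greyunet:::conv3_forward(X, pars, geom44),
           function(dY, res) greyunet:::conv3_backward(dY, res, pars, geom44, 2)$dX,
           X, 3)
})

test_that("max pooling selects block maxima and routes gradients to them", {
  set.seed(22)
  X <- matrix(rnorm(16 * 2), 16, 2)
  res <- greyunet:::pool_forward(X, geom44)
  expect_equal(dim(res$out), c(4L, 2L))
  img <- array(X, c(4, 4, 2))
  for (c in 1:2)
    expect_equal(matrix(res$out[, c], 2, 2),
                 matrix(c(max(img[1:2, 1:2, c]), max(img[3:4, 1:2, c]),
                          max(img[1:2, 3:4, c]), max(img[3:4, 3:4, c])), 2, 2))
  fd_check(function(X) greyunet:::pool_forward(X, geom44),
           function(dY, res) greyunet:::pool_backward(dY, res, geom44, 16),
           X, 2)
})

test_that("transposed convolution doubles resolution and back-propagates exactly", {
  set.seed(23)
  pars <- greyunet:::upconv_init(3, 2)
  X <- matrix(rnorm(4 * 3), 4, 3)       # 2x2 input
  fwd <- function(X) greyunet:::upconv_forward(X, pars, geom44)
  expect_equal(dim(fwd(X)$out), c(16L, 2L))
  fd_check(fwd,
           function(dY, res) greyunet:::upconv_backward(dY, res, pars, geom44)$dX,
           X, 2)
})

test_that("batch normalization standardizes in training and back-propagates exactly", {
  set.seed(24)
  pars <- greyunet:::bn_init(3)
  pars$gamma <- runif(3, 0.5, 1.5); pars$beta <- rnorm(3)
  X <- matrix(rnorm(20 * 3, mean = 2, sd = 3), 20, 3)
  res <- greyunet:::bn_forward(X, pars, training = TRUE)
  expect_equal(colMeans(res$out), pars$beta)
  expect_equal(apply(res$out, 2, function(v) sqrt(mean((v - mean(v))^2))),
               pars$gamma, tolerance = 1e-3)
  fd_check(function(X) greyunet:::bn_forward(X, pars, training = TRUE),
           function(dY, res) greyunet:::bn_backward(dY, res, pars)$dX,
           X, 3, tol = 1e-4)
})

test_that("softmax/sigmoid heads and their backward passes agree with finite differences", {
  set.seed(25)
  Z <- matrix(rnorm(12), 4, 3)
  P <- greyunet:::softmax_rows(Z)
  expect_equal(rowSums(P), rep(1, 4))
  dP <- matrix(rnorm(12), 4, 3)
  dZ <- greyunet:::softmax_backward(dP, P)
  for (i in sample(12, 4)) {
    f <- function(v) { Z2 <- Z; Z2[i] <- v; sum(greyunet:::softmax_rows(Z2) * dP) }
    expect_equal(dZ[i], num_deriv(f, Z[i]), tolerance = 1e-5)
  }
  S <- greyunet:::sigmoid_rows(Z)
  dZs <- greyunet:::sigmoid_backward(dP, S)
  for (i in sample(12, 4)) {
    f <- function(v) { Z2 <- Z; Z2[i] <- v; sum(greyunet:::sigmoid_rows(Z2) * dP) }
    expect_equal(dZs[i], num_deriv(f, Z[i]), tolerance = 1e-5)
  }
})

test_that("dropout shields with the configured probability and rescales", {
  set.seed(26)
  X <- matrix(1, 200, 50)
  res <- greyunet:::dropout_forward(X, 0.5, training = TRUE)
  kept <- mean(res$out > 0)
  expect_equal(kept, 0.5, tolerance = 0.02)
  expect_true(all(res$out %in% c(0, 2)))          # inverted scaling 1/(1-P)
  expect_identical(greyunet:::dropout_forward(X, 0.5, training = FALSE)$out, X)
  expect_identical(greyunet:::dropout_forward(X, 0, training = TRUE)$out, X)
})
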