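test_that("pixel entropy terms match direct evaluation of the channel sums", {
  # oracle: E and E' written out by hand for the benign fixed point
  r <- pixel_entropy_terms(rep(0.5, 3), rep(0.5, 3))
  expect_equal(r$E, 3 * 0.5 * log(0.5))       # ~ -1.0397
  expect_equal(r$Eprime, 3 * 0.5 * log(0.5))

  r <- pixel_entropy_terms(c(1, 1, 1), rep(1 - 1e-7, 3))
  expect_equal(r$E, 0, tolerance = 1e-6)
  expect_equal(r$Eprime, 0, tolerance = 1e-6)

  r <- pixel_entropy_terms(c(0, 0, 0), rep(1e-7, 3))
  expect_identical(r$E * 0, 0)   # zero-weight terms contribute exactly 0
  expect_equal(r$Eprime, 0, tolerance = 1e-6)

  expect_error(pixel_entropy_terms(c(0, 1), c(0.5, 0.5, 0.5)), "3 channels")
})

test_that("expanded cross-entropy: perfect and benign fixed points", {
  y0 <- array(0, c(1, 1, 3))
  expect_lt(expanded_cross_entropy(y0, array(1e-7, c(1, 1, 3))), 1e-5)
  yb <- array(0.5, c(1, 1, 3))
  # -sum_k [0.5 log 0.5 + 0.5 log 0.5] = 3 log 2 ~ 2.079
  expect_equal(expanded_cross_entropy(yb, array(0.5, c(1, 1, 3))), 3 * log(2))
  expect_error(expanded_cross_entropy(yb, array(0.5, c(1, 2, 3))), "identical dimensions")
  expect_error(expanded_cross_entropy(yb, array(NaN, c(1, 1, 3))), "NaN")
})

test_that("expanded cross-entropy equals the mean of the per-pixel case loss", {
  set.seed(8)
  for (rep in 1:5) {
    h <- sample(2:4, 1); w <- sample(2:4, 1); n <- sample(1:3, 1)
    mask_classes <- array(sample(0:2, h * w * n, replace = TRUE), c(h, w, n))
    y <- array(c(0, 0.5, 1)[mask_classes + 1], c(h, w, n))
    Y <- aperm(array(y, c(h, w, n, 3)), c(1, 2, 4, 3))
    P <- array(runif(h * w * 3 * n, 0.05, 0.95), c(h, w, 3, n))
    # oracle: loop per pixel/channel over the case-form loss
    acc <- 0
    for (i in seq_len(n)) for (r in seq_len(h)) for (cc in seq_len(w)) for (k in 1:3)
      acc <- acc + per_pixel_case_loss(Y[r, cc, k, i], P[r, cc, k, i])
    expect_equal(expanded_cross_entropy(Y, P), acc / (n * h * w))
  }
})

test_that("loss is non-negative and near zero only at hard targets", {
  set.seed(9)
  Y <- array(sample(c(0, 0.5, 1), 48, replace = TRUE), c(4, 4, 3))
  P <- array(runif(48), c(4, 4, 3))
  expect_gte(expanded_cross_entropy(Y, P), 0)
  # at the target values, only the benign channels keep a loss floor
  Pstar <- Y
  floor_loss <- expanded_cross_entropy(Y, Pstar)
  n_benign_ch <- sum(Y == 0.5)
  expect_equal(floor_loss, n_benign_ch * log(2) / 16, tolerance = 1e-4)
})

test_that("three-channel ECE is exactly 3x the binary cross-entropy, in value and gradient", {
  set.seed(10)
  for (i in 1:25) {
    y <- sample(c(0, 0.5, 1), 1)
    p <- runif(1, 0.02, 0.98)
    e3 <- expanded_cross_entropy(array(y, c(1, 1, 3)), array(p, c(1, 1, 3)),
                                 gradient = TRUE)
    b1 <- binary_cross_entropy(y, p, gradient = TRUE)
    expect_equal(as.numeric(e3) / as.numeric(b1), 3)
    # gradient w.r.t. the shared scalar p: sum of the 3 channel gradients
    expect_equal(sum(attr(e3, "gradient")) / sum(attr(b1, "gradient")), 3)
    # and numerically, against central differences
    g_num <- num_deriv(function(q)
      expanded_cross_entropy(array(y, c(1, 1, 3)), array(q, c(1, 1, 3))), p)
    expect_equal(sum(attr(e3, "gradient")), g_num, tolerance = 1e-5)
  }
})

test_that("per-pixel case loss agrees with the general formula and is symmetric for benign", {
  set.seed(12)
  p <- runif(40, 0.01, 0.99)
  for (y in c(0, 0.5, 1)) {
    direct <- -y * log(p) - (1 - y) * log(1 - p)
    expect_equal(per_pixel_case_loss(y, p), direct)
  }
  expect_equal(per_pixel_case_loss(0.5, p), per_pixel_case_loss(0.5, 1 - p))
  expect_error(per_pixel_case_loss(0.3, 0.5), "0, 0.5, 1")
  expect_error(per_pixel_case_loss(1, 0), "inside \\(0, 1\\)")
})

test_that("grid-search oracle reproduces the analytic minima of the three cases", {
  p <- seq(1e-6, 1 - 1e-6, by = 1e-6)
  expect_equal(p[which.min(per_pixel_case_loss(0.5, p))], 0.5, tolerance = 2e-6)
  expect_equal(min(per_pixel_case_loss(0.5, p)), -0.5 * log(1 / 4))  # log 2
  expect_equal(p[which.min(per_pixel_case_loss(1, p))], 1, tolerance = 2e-6)
  expect_equal(p[which.min(per_pixel_case_loss(0, p))], 0, tolerance = 2e-6)
})

test_that("constrained benign minimum sits at p = 1/3 per channel", {
  r <- constrained_benign_minimum()
  expect_equal(r$p, rep(1 / 3, 3), tolerance = 1e-5)
  expect_equal(sum(r$p), 1, tolerance = 1e-9)
  expect_equal(r$grey, 85, tolerance = 1e-3)
  expect_equal(r$alpha, 2 / 3, tolerance = 1e-5)

  # independent oracle: dense grid over the simplex
  p1 <- seq(0.01, 0.98, by = 0.002)
  grid <- expand.grid(p1 = p1, p2 = p1)
  grid$p3 <- 1 - grid$p1 - grid$p2
  grid <- grid[grid$p3 > 0.01, ]
  obj <- -0.5 * (log(grid$p1 * (1 - grid$p1)) + log(grid$p2 * (1 - grid$p2)) +
                   log(grid$p3 * (1 - grid$p3)))
  best <- grid[which.min(obj), ]
  expect_equal(unlist(best, use.names = FALSE), rep(1 / 3, 3), tolerance = 5e-3)
  expect_lte(r$value, min(obj))
})
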