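# Minimal CNN engine used by the expanded U-Net.
#
# Feature maps live in a flat matrix layout: a batch of B images of size
# H x W with C channels is a (B*H*W) x C matrix, rows ordered image-major
# then column-major within each image (R's native matrix order). Spatial
# operators become gathers (row indexing) plus BLAS matmuls; a gather with
# zero padding is its own adjoint under the opposite offset, which keeps the
# backward passes exact and vectorized.

# ---- geometry ----------------------------------------------------------

# Row-index tables for one (B, H, W) geometry. The sentinel row n+1 holds
# zeros (matrices are padded with a zero row before gathering).
nn_geometry <- function(B, H, W) {
  n1 <- H * W
  y <- rep.int(seq_len(H), W)          # image row of each pixel
  x <- rep(seq_len(W), each = H)       # image column
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  conv_idx <- lapply(seq_len(9), function(o) {
    yy <- y + offs$dy[o]; xx <- x + offs$dx[o]
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    i1 <- ifelse(ok, (xx - 1) * H + yy, NA_integer_)
    idx <- rep(i1, B) + rep((0:(B - 1)) * n1, each = n1)
    idx[is.na(idx)] <- B * n1 + 1L
    idx
  })
  # offset o = (dy,dx); opposite offset index within the 3x3 enumeration
  conv_opp <- vapply(seq_len(9), function(o)
    which(offs$dy == -offs$dy[o] & offs$dx == -offs$dx[o]), integer(1))

  H2 <- H %/% 2; W2 <- W %/% 2
  yo <- rep.int(seq_len(H2), W2); xo <- rep(seq_len(W2), each = H2)
  pool_idx <- lapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(d) {
    i1 <- (2 * xo - 2 + d[2]) * H + (2 * yo - 1 + d[1])
    rep(i1, B) + rep((0:(B - 1)) * n1, each = H2 * W2)
  })
  # upconv: for input pixel (yo, xo) at half resolution, the output row of
  # sub-position (a, b) in the 2x2 block at full resolution
  up_idx <- lapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(d) {
    i1 <- (2 * xo - 2 + d[2]) * H + (2 * yo - 1 + d[1])
    rep(i1, B) + rep((0:(B - 1)) * n1, each = H2 * W2)
  })
  list(B = B, H = H, W = W, n = B * n1,
       conv_idx = conv_idx, conv_opp = conv_opp,
       pool_idx = pool_idx, up_idx = up_idx,
       n_half = B * H2 * W2)
}

pad_zero_row <- function(X) rbind(X, 0)

# ---- 3x3 "same" convolution -------------------------------------------

conv3_init <- function(c_in, c_out, rng_sd = sqrt(2 / (9 * c_in))) {
  list(W = matrix(stats::rnorm(9 * c_in * c_out, sd = rng_sd), 9 * c_in, c_out),
       b = numeric(c_out))
}

# im2col: gather the 9 shifted views and stack as columns
conv3_im2col <- function(X, geom) {
  Xz <- pad_zero_row(X)
  do.call(cbind, lapply(geom$conv_idx, function(idx) Xz[idx, , drop = FALSE]))
}

conv3_forward <- function(X, pars, geom) {
  Xcol <- conv3_im2col(X, geom)
  Y <- Xcol %*% pars$W
  Y <- sweep(Y, 2, pars$b, "+")
  list(out = Y, Xcol = Xcol)
}

conv3_backward <- function(dY, cache, pars, geom, c_in) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(pars$W)
  dX <- matrix(0, geom$n, c_in)
  for (o in seq_len(9)) {
    blk <- dXcol[, ((o - 1) * c_in + 1):(o * c_in), drop = FALSE]
    dX <- dX + pad_zero_row(blk)[geom$conv_idx[[geom$conv_opp[o]]], , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- 1x1 convolution (the output head) --------------------------------

conv1_init <- function(c_in, c_out) {
  list(W = matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
       b = numeric(c_out))
}

conv1_forward <- function(X, pars) {
  list(out = sweep(X %*% pars$W, 2, pars$b, "+"), X = X)
}

conv1_backward <- function(dY, cache, pars) {
  list(dX = dY %*% t(pars$W), dW = crossprod(cache$X, dY), db = colSums(dY))
}

# ---- batch normalization ----------------------------------------------

bn_init <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out),
       rmean = numeric(c_out), rvar = rep(1, c_out))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_forward <- function(X, pars, training) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, istd, "*")
    out <- sweep(sweep(xhat, 2, pars$gamma, "*"), 2, pars$beta, "+")
    list(out = out, xhat = xhat, istd = istd, xc = xc,
         new_rmean = BN_MOMENTUM * pars$rmean + (1 - BN_MOMENTUM) * mu,
         new_rvar = BN_MOMENTUM * pars$rvar + (1 - BN_MOMENTUM) * v)
  } else {
    xhat <- sweep(sweep(X, 2, pars$rmean), 2, 1 / sqrt(pars$rvar + BN_EPS), "*")
    list(out = sweep(sweep(xhat, 2, pars$gamma, "*"), 2, pars$beta, "+"))
  }
}

bn_backward <- function(dY, cache, pars) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, pars$gamma, "*")
  # standard batch-norm backward, fused form
  t1 <- colSums(dxhat)
  t2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(dxhat, 2, t1 / n) - sweep(cache$xhat, 2, t2 / n, "*")
  dX <- sweep(dX, 2, cache$istd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations / dropout --------------------------------------------

lrelu_forward <- function(X, slope) {
  list(out = pmax(X, 0) + slope * pmin(X, 0), X = X)
}

lrelu_backward <- function(dY, cache, slope) {
  dY * ifelse(cache$X > 0, 1, slope)
}

dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate),
                 nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# ---- 2x2 max pooling ---------------------------------------------------

pool_forward <- function(X, geom) {
  Xs <- lapply(geom$pool_idx, function(idx) X[idx, , drop = FALSE])
  M <- pmax(Xs[[1]], Xs[[2]], Xs[[3]], Xs[[4]])
  list(out = M, Xs = Xs, M = M)
}

pool_backward <- function(dY, cache, geom, n_full) {
  dX <- matrix(0, n_full, ncol(dY))
  taken <- matrix(FALSE, nrow(dY), ncol(dY))
  for (q in 1:4) {
    sel <- (cache$Xs[[q]] == cache$M) & !taken   # first-max wins on ties
    taken <- taken | sel
    dX[geom$pool_idx[[q]], ] <- dY * sel
  }
  dX
}

# ---- 2x2 stride-2 transposed convolution ------------------------------

upconv_init <- function(c_in, c_out) {
  list(W = lapply(1:4, function(q)
         matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out)),
       b = numeric(c_out))
}

upconv_forward <- function(X, pars, geom) {
  # kernel 2, stride 2: the four sub-positions tile the output exactly once
  Y <- matrix(0, geom$n, ncol(pars$W[[1]]))
  for (q in 1:4) Y[geom$up_idx[[q]], ] <- X %*% pars$W[[q]]
  Y <- sweep(Y, 2, pars$b, "+")
  list(out = Y, X = X)
}

upconv_backward <- function(dY, cache, pars, geom) {
  dX <- 0
  dW <- vector("list", 4)
  for (q in 1:4) {
    dYq <- dY[geom$up_idx[[q]], , drop = FALSE]
    dX <- dX + dYq %*% t(pars$W[[q]])
    dW[[q]] <- crossprod(cache$X, dYq)
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

# ---- output heads ------------------------------------------------------

softmax_rows <- function(Z) {
  Zm <- Z - apply(Z, 1, max)
  E <- exp(Zm)
  E / rowSums(E)
}

softmax_backward <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

sigmoid_rows <- function(Z) 1 / (1 + exp(-Z))

sigmoid_backward <- function(dP, P) dP * P * (1 - P)
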