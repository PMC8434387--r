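# Internal layer primitives.
#
# Feature maps live in arrays of dim c(C, W, N): C channels, W timesteps,
# N = 3 * B sequences (the 3 sensor axes of each of B samples, axis-fastest:
# n = (b - 1) * 3 + h).  Convolutions have kernel size 1 along the axis
# dimension and 1 or 3 along time, so every axis is an independent 1-D
# sequence and both convolutions reduce to BLAS matrix products against
# time-shifted views; shifting commutes with the channel-mixing product, so
# the taps are applied to the product's output rather than to copies of the
# input.  Each *_fwd returns list(out, cache); each *_bwd takes the upstream
# gradient and the cache and returns gradients for input and parameters.
# All of this is deliberately dependency-free: the network is the package's
# core contribution and runs on plain R matrix algebra.

mat3 <- function(x) { dim(x) <- c(dim(x)[1L], prod(dim(x)[-1L])); x }

shift_left <- function(x) { # y[, w, ] = x[, w - 1, ] (zero-padded)
  W <- dim(x)[2L]
  y <- array(0, dim(x))
  y[, 2:W, ] <- x[, 1:(W - 1L), , drop = FALSE]
  y
}

shift_right <- function(x) { # y[, w, ] = x[, w + 1, ] (zero-padded)
  W <- dim(x)[2L]
  y <- array(0, dim(x))
  y[, 1:(W - 1L), ] <- x[, 2:W, , drop = FALSE]
  y
}

kslice <- function(K, j) array(K[, , j], dim(K)[1:2]) # Cout x Cin matrix

conv1x3_fwd <- function(X, K, b) {
  d <- dim(X)
  Cout <- dim(K)[1L]
  W <- d[2L]
  # one stacked product for all three taps, then fused shifted accumulation
  Kstack <- rbind(kslice(K, 1), kslice(K, 2), kslice(K, 3))
  P <- Kstack %*% mat3(X)
  Y <- .conv_tap_add(P, b, Cout, W, d[3L])
  dim(Y) <- c(Cout, W, d[3L])
  list(out = Y, cache = list(X = X, K = K))
}

conv1x3_bwd <- function(dY, cache) {
  X <- cache$X
  K <- cache$K
  d <- dim(dY)
  Xm <- mat3(X)
  dYm <- mat3(dY)
  # dK_j = sum_w dY[, w, ] X[, w - j_offset, ]^T: shift dY, not X
  sh <- .shift_both(dY, d[1L], d[2L], d[3L])
  dYl <- sh$left   # dYl[, w, ] = dY[, w - 1, ]
  dYr <- sh$right  # dYr[, w, ] = dY[, w + 1, ]
  dim(dYl) <- dim(dYr) <- c(d[1L], d[2L] * d[3L])
  dK <- array(0, dim(K))
  dK[, , 1] <- tcrossprod(dYr, Xm)  # pairs dY[, w+1, ] with X[, w, ]
  dK[, , 2] <- tcrossprod(dYm, Xm)
  dK[, , 3] <- tcrossprod(dYl, Xm)  # pairs dY[, w-1, ] with X[, w, ]
  db <- .rowSums(dYm, nrow(dYm), ncol(dYm))
  # dX[, w, ] = K2^T dY[, w, ] + K1^T dY[, w+1, ] + K3^T dY[, w-1, ]
  dX <- crossprod(kslice(K, 2), dYm) +
    crossprod(kslice(K, 1), dYr) +
    crossprod(kslice(K, 3), dYl)
  dim(dX) <- dim(X)
  list(dX = dX, dK = dK, db = db)
}

conv1x1_fwd <- function(X, K, b) {
  Y <- K %*% mat3(X) + b
  dim(Y) <- c(nrow(K), dim(X)[2L], dim(X)[3L])
  list(out = Y, cache = list(X = X, K = K))
}

conv1x1_bwd <- function(dY, cache) {
  X <- cache$X
  dYm <- mat3(dY)
  dX <- crossprod(cache$K, dYm)
  dim(dX) <- dim(X)
  list(dX = dX,
       dK = tcrossprod(dYm, mat3(X)),
       db = .rowSums(dYm, nrow(dYm), ncol(dYm)))
}

# Batch normalization over channels (statistics pooled over time, axes and
# batch).  Population variance is used both for normalization and for the
# running statistics; eval mode normalizes with the running statistics.
bn_fwd <- function(X, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  Xm <- mat3(X)
  if (training) {
    f <- .bn_train_fwd(Xm, gamma, beta, eps)
    run$mean <- (1 - momentum) * run$mean + momentum * f$mean
    run$var <- (1 - momentum) * run$var + momentum * f$var
    Y <- f$y
    dim(Y) <- d
    return(list(out = Y, run = run,
                cache = list(xhat = f$xhat, inv = f$inv, gamma = gamma,
                             d = d, training = TRUE)))
  }
  inv <- 1 / sqrt(run$var + eps)
  xhat <- (Xm - run$mean) * inv
  Y <- gamma * xhat + beta
  dim(Y) <- d
  list(out = Y, run = run,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d,
                    training = FALSE))
}

bn_bwd <- function(dY, cache) {
  d <- cache$d
  dYm <- mat3(dY)
  if (cache$training) {
    b <- .bn_train_bwd(dYm, cache$xhat, cache$inv, cache$gamma)
    dX <- b$dX
    dim(dX) <- d
    return(list(dX = dX, dgamma = b$dgamma, dbeta = b$dbeta))
  }
  C <- d[1L]
  m <- prod(d[-1L])
  dXm <- dYm * (cache$gamma * cache$inv)
  dim(dXm) <- d
  list(dX = dXm,
       dgamma = .rowSums(dYm * cache$xhat, C, m),
       dbeta = .rowSums(dYm, C, m))
}

relu_fwd <- function(X) {
  neg <- X <= 0
  X[neg] <- 0
  list(out = X, cache = neg)
}

relu_bwd <- function(dY, neg) {
  dY[neg] <- 0
  dY
}

# Max pooling along time, kernel 2 stride 2 (the axis dimension is never
# pooled, so axis identity survives to the attention maps).
maxpool2_fwd <- function(X) {
  d <- dim(X)
  stopifnot(d[2L] %% 2L == 0L)
  r <- .maxpool2_fwd(X, d[1L], d[2L], d[3L])
  out <- r$out
  dim(out) <- c(d[1L], d[2L] %/% 2L, d[3L])
  list(out = out, cache = list(first_wins = r$first, d = d))
}

maxpool2_bwd <- function(dY, cache) {
  d <- cache$d
  dX <- .maxpool2_bwd(dY, cache$first_wins, d[1L], d[2L], d[3L])
  dim(dX) <- d
  dX
}

# Global average pooling over time and axes: (C, W, 3B) -> (C, B).
gap_fwd <- function(X) {
  d <- dim(X)
  B <- d[3L] %/% 3L
  tmp <- X
  dim(tmp) <- c(d[1L], d[2L] * 3L, B)
  out <- colSums(aperm(tmp, c(2L, 1L, 3L))) / (d[2L] * 3L)
  dim(out) <- c(d[1L], B)
  list(out = out, cache = d)
}

gap_bwd <- function(dout, d) {
  B <- d[3L] %/% 3L
  m <- d[2L] * 3L
  dX <- dout[, rep(seq_len(B), each = m), drop = FALSE] / m
  dim(dX) <- d
  dX
}

fc_fwd <- function(x, W, b) {
  list(out = W %*% x + b, cache = list(x = x, W = W))
}

fc_bwd <- function(dY, cache) {
  list(dX = crossprod(cache$W, dY),
       dW = tcrossprod(dY, cache$x),
       db = .rowSums(dY, nrow(dY), ncol(dY)))
}

sigmoid <- function(x) stats::plogis(x)
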