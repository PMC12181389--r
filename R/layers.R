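# Minimal reverse-mode layer machinery for the compact networks used here.
# Public arrays are (H, W, C, N); internally the stack runs on (H, W, N, C),
# which lets im2col/col2im slice padded arrays without transposition copies.
# Each layer is an environment carrying parameters, Adam state, and the
# forward cache; convolutions run as im2col + BLAS matrix products.

new_layer <- function(type, ...) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- list()
  l$grads <- list()
  l$adam <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  l
}

# x is (H, W, N, C); rows of the patch matrix run (h, w, n), columns (offset, c)
im2col <- function(x, H, W, N, C) {
  xp <- array(0, c(H + 2L, W + 2L, N, C))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  col <- matrix(0, H * W * N, 9L * C)
  o <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    o <- o + 1L
    sl <- xp[dy + (1:H), dx + (1:W), , , drop = FALSE]
    dim(sl) <- c(H * W * N, C)
    col[, ((o - 1L) * C + 1L):(o * C)] <- sl
  }
  col
}

col2im <- function(dcol, H, W, N, C) {
  dxp <- array(0, c(H + 2L, W + 2L, N, C))
  o <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    o <- o + 1L
    blk <- dcol[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dim(blk) <- c(H, W, N, C)
    dxp[dy + (1:H), dx + (1:W), , ] <- dxp[dy + (1:H), dx + (1:W), , , drop = FALSE] + blk
  }
  dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

layer_conv <- function(in_channels, filters) {
  l <- new_layer("conv", C = in_channels, F = filters)
  fan_in <- 9L * in_channels
  l$params$W <- matrix(rnorm(fan_in * filters, 0, sqrt(2 / fan_in)), fan_in, filters)
  l$params$b <- numeric(filters)
  l
}

conv_forward <- function(l, x, train) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  col <- im2col(x, H, W, N, C)
  out <- col %*% l$params$W
  out <- sweep(out, 2L, l$params$b, "+")
  dim(out) <- c(H, W, N, l$F)
  l$cache <- list(col = col, H = H, W = W, N = N, C = C)
  out
}

conv_backward <- function(l, dout) {
  cc <- l$cache
  dmat <- dout
  dim(dmat) <- c(cc$H * cc$W * cc$N, l$F)
  l$grads$W <- crossprod(cc$col, dmat)
  l$grads$b <- colSums(dmat)
  dcol <- tcrossprod(dmat, l$params$W)
  col2im(dcol, cc$H, cc$W, cc$N, cc$C)
}

layer_batchnorm <- function(channels, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("batchnorm", C = channels, momentum = momentum, eps = eps)
  l$params$gamma <- rep(1, channels)
  l$params$beta <- numeric(channels)
  l$run_mean <- numeric(channels)
  l$run_var <- rep(1, channels)
  l
}

bn_forward <- function(l, x, train) {
  d <- dim(x)
  out <- x
  xhat <- x
  inv_std <- numeric(l$C)
  for (c in seq_len(l$C)) {
    xc <- x[, , , c, drop = FALSE]
    if (train) {
      mu <- mean(xc)
      v <- mean((xc - mu)^2)
      l$run_mean[c] <- (1 - l$momentum) * l$run_mean[c] + l$momentum * mu
      l$run_var[c] <- (1 - l$momentum) * l$run_var[c] + l$momentum * v
    } else {
      mu <- l$run_mean[c]; v <- l$run_var[c]
    }
    inv_std[c] <- 1 / sqrt(v + l$eps)
    xh <- (xc - mu) * inv_std[c]
    xhat[, , , c] <- xh
    out[, , , c] <- l$params$gamma[c] * xh + l$params$beta[c]
  }
  l$cache <- list(xhat = xhat, inv_std = inv_std, M = prod(d[-4]), train = train)
  out
}

bn_backward <- function(l, dout) {
  cc <- l$cache
  dx <- dout
  dgamma <- numeric(l$C); dbeta <- numeric(l$C)
  for (c in seq_len(l$C)) {
    dc <- dout[, , , c, drop = FALSE]
    xh <- cc$xhat[, , , c, drop = FALSE]
    dgamma[c] <- sum(dc * xh)
    dbeta[c] <- sum(dc)
    if (cc$train) {
      dx[, , , c] <- (l$params$gamma[c] * cc$inv_std[c] / cc$M) *
        (cc$M * dc - dbeta[c] - xh * dgamma[c])
    } else {
      dx[, , , c] <- l$params$gamma[c] * cc$inv_std[c] * dc
    }
  }
  l$grads$gamma <- dgamma
  l$grads$beta <- dbeta
  dx
}

layer_relu <- function() new_layer("relu")

relu_forward <- function(l, x, train) {
  l$cache <- x > 0
  x * l$cache
}

layer_pool <- function() new_layer("pool")

pool_forward <- function(l, x, train) {
  d <- dim(x)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ri <- seq_len(2L * H2); ci <- seq_len(2L * W2)
  x <- x[ri, ci, , , drop = FALSE]
  s <- list(x[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
            x[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2), , , drop = FALSE],
            x[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE],
            x[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2), , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4L)
  for (i in 1:4) {
    masks[[i]] <- (s[[i]] == m) & !taken
    taken <- taken | masks[[i]]
  }
  l$cache <- list(masks = masks, in_dim = d, H2 = H2, W2 = W2)
  m
}

pool_backward <- function(l, dout) {
  cc <- l$cache
  dx <- array(0, cc$in_dim)
  H2 <- cc$H2; W2 <- cc$W2
  rows <- list(seq(1, 2 * H2, 2), seq(2, 2 * H2, 2), seq(1, 2 * H2, 2), seq(2, 2 * H2, 2))
  cols <- list(seq(1, 2 * W2, 2), seq(1, 2 * W2, 2), seq(2, 2 * W2, 2), seq(2, 2 * W2, 2))
  for (i in 1:4) {
    dx[rows[[i]], cols[[i]], , ] <- dout * cc$masks[[i]]
  }
  dx
}

layer_dropout <- function(rate) new_layer("dropout", rate = rate)

dropout_forward <- function(l, x, train) {
  if (!train || l$rate <= 0) {
    l$cache <- NULL
    return(x)
  }
  keep <- 1 - l$rate
  mask <- array(runif(length(x)) < keep, dim(x)) / keep
  l$cache <- mask
  x * mask
}

layer_flatten <- function() new_layer("flatten")

flatten_forward <- function(l, x, train) {
  d <- dim(x)                       # (H, W, N, C)
  l$cache <- d
  x <- aperm(x, c(1L, 2L, 4L, 3L))  # per-sample columns
  dim(x) <- c(d[1] * d[2] * d[4], d[3])
  x
}

flatten_backward <- function(l, dout) {
  d <- l$cache
  dim(dout) <- c(d[1], d[2], d[4], d[3])
  aperm(dout, c(1L, 2L, 4L, 3L))
}

layer_dense <- function(in_dim, out_dim) {
  l <- new_layer("dense", in_dim = in_dim, out_dim = out_dim)
  l$params$W <- matrix(rnorm(in_dim * out_dim, 0, sqrt(2 / in_dim)), out_dim, in_dim)
  l$params$b <- numeric(out_dim)
  l
}

dense_forward <- function(l, x, train) {
  l$cache <- x
  l$params$W %*% x + l$params$b
}

dense_backward <- function(l, dout) {
  l$grads$W <- tcrossprod(dout, l$cache)
  l$grads$b <- rowSums(dout)
  crossprod(l$params$W, dout)
}

layer_softmax <- function() new_layer("softmax")

softmax_forward <- function(l, x, train) {
  z <- sweep(x, 2L, apply(x, 2L, max), "-")
  e <- exp(z)
  p <- sweep(e, 2L, colSums(e), "/")
  l$cache <- p
  p
}

# QuantClass head layer: affine angle encoding theta_i = scale * tanh(A x + b)
# per qubit, closed-form circuit probabilities, parameter-shift backward.
# The squash scale is pi/2 so the per-qubit marginal (1 + sin theta)/2 is
# monotone in the pre-activation with asymptotes 0 and 1; a scale of pi puts
# boundary attractors at theta = +-pi where the marginal folds back to 1/2 and
# the gradient vanishes.
layer_qclass <- function(mode = "functional", s = pi / 2, jitter_sigma = 0,
                         scale = pi / 2) {
  l <- new_layer("qclass", mode = mode, s = s, jitter_sigma = jitter_sigma,
                 scale = scale)
  l$params$A <- diag(2)
  l$params$b <- numeric(2)
  l
}

qclass_forward_layer <- function(l, x, train) {
  z <- l$params$A %*% x + l$params$b
  theta <- l$scale * tanh(z)
  if (train && l$jitter_sigma > 0) {
    theta <- theta + rnorm(length(theta), 0, l$jitter_sigma)
  }
  if (l$mode == "literal") theta[2L, ] <- theta[1L, ]
  p <- qclass_prob_matrix(theta[1L, ], theta[2L, ], l$mode)
  l$cache <- list(x = x, z = z, theta = theta)
  p
}

qclass_backward_layer <- function(l, dout) {
  cc <- l$cache
  th1 <- cc$theta[1L, ]; th2 <- cc$theta[2L, ]
  s <- l$s
  den <- 2 * sin(s)
  if (l$mode == "literal") {
    # shared angle: shift the single parameter on both qubits
    J <- (qclass_prob_matrix(th1 + s, th1 + s, l$mode) -
          qclass_prob_matrix(th1 - s, th1 - s, l$mode)) / den
    dth <- rbind(colSums(J * dout), 0)
  } else {
    J1 <- (qclass_prob_matrix(th1 + s, th2, l$mode) -
           qclass_prob_matrix(th1 - s, th2, l$mode)) / den
    J2 <- (qclass_prob_matrix(th1, th2 + s, l$mode) -
           qclass_prob_matrix(th1, th2 - s, l$mode)) / den
    dth <- rbind(colSums(J1 * dout), colSums(J2 * dout))
  }
  dz <- dth * l$scale * (1 - tanh(cc$z)^2)
  l$grads$A <- tcrossprod(dz, cc$x)
  l$grads$b <- rowSums(dz)
  crossprod(l$params$A, dz)
}

layer_forward <- function(l, x, train) {
  switch(l$type,
         conv = conv_forward(l, x, train),
         batchnorm = bn_forward(l, x, train),
         relu = relu_forward(l, x, train),
         pool = pool_forward(l, x, train),
         dropout = dropout_forward(l, x, train),
         flatten = flatten_forward(l, x, train),
         dense = dense_forward(l, x, train),
         softmax = softmax_forward(l, x, train),
         qclass = qclass_forward_layer(l, x, train),
         qt_stop("unknown layer type ", l$type))
}

layer_backward <- function(l, dout) {
  switch(l$type,
         conv = conv_backward(l, dout),
         batchnorm = bn_backward(l, dout),
         relu = dout * l$cache,
         pool = pool_backward(l, dout),
         dropout = if (is.null(l$cache)) dout else dout * l$cache,
         flatten = flatten_backward(l, dout),
         dense = dense_backward(l, dout),
         softmax = dout,   # fused softmax + cross-entropy: dout is dlogits
         qclass = qclass_backward_layer(l, dout),
         qt_stop("unknown layer type ", l$type))
}

adam_step <- function(l, lr, beta1, beta2, eps, t) {
  for (nm in names(l$grads)) {
    g <- l$grads[[nm]]
    if (is.null(l$adam[[nm]])) {
      l$adam[[nm]] <- list(m = g * 0, v = g * 0)
    }
    st <- l$adam[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    l$adam[[nm]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
}
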