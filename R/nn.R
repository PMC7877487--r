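# Minimal CNN engine: im2col convolutions, batch normalization, Adam.
#
# Feature maps are stored as (C*H*W) x B matrices, one column per image,
# channel index fastest (value at channel c, row h, col w sits at
# c + C*((h-1) + H*(w-1))). im2col gather/scatter indices are precomputed per
# layer geometry so every convolution forward/backward is a single BLAS
# matrix product plus one indexed gather (forward) or one rowsum scatter
# (backward). This keeps 108x108 training tractable on one CPU without any
# compiled code.

conv_geom <- function(C_in, H, W, C_out, k, stride = 1L, pad = 0L) {
  H_out <- (H + 2L * pad - k) %/% stride + 1L
  W_out <- (W + 2L * pad - k) %/% stride + 1L
  if (H_out < 1L || W_out < 1L) {
    stop(sprintf("conv geometry collapses: %dx%d with k=%d stride=%d pad=%d", H, W, k, stride, pad))
  }
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad

  # interior indices of the padded buffer, in the layout order of the input
  g <- expand.grid(c = seq_len(C_in), h = seq_len(H), w = seq_len(W))
  int_idx <- g$c + C_in * ((g$h + pad - 1L) + Hp * (g$w + pad - 1L))

  # col_idx[r, o]: padded-buffer index feeding row r (= kernel element
  # (c, dh, dw)) of output pixel o (= (ho, wo), ho fastest)
  r <- expand.grid(c = seq_len(C_in), dh = seq_len(k), dw = seq_len(k))
  o <- expand.grid(ho = seq_len(H_out), wo = seq_len(W_out))
  hp <- outer(r$dh, (o$ho - 1L) * stride, `+`) # padded row, 1-based
  wp <- outer(r$dw, (o$wo - 1L) * stride, `+`)
  col_idx <- as.integer(r$c + C_in * ((hp - 1L) + Hp * (wp - 1L)))

  list(
    C_in = C_in, H = H, W = W, C_out = C_out, k = k,
    stride = as.integer(stride), pad = as.integer(pad),
    H_out = H_out, W_out = W_out, npix = H_out * W_out,
    n_padded = Hp * Wp * C_in, k2C = k * k * C_in,
    int_idx = as.integer(int_idx), col_idx = col_idx,
    padded = pad > 0L
  )
}

conv_init <- function(geom, seed_stream = NULL) {
  # He initialization: appropriate for the ReLU nonlinearity that follows
  list(
    W = matrix(
      stats::rnorm(geom$C_out * geom$k2C, sd = sqrt(2 / geom$k2C)),
      nrow = geom$C_out
    ),
    b = numeric(geom$C_out)
  )
}

conv_forward <- function(geom, par, X) {
  B <- ncol(X)
  Xp <- if (geom$padded) nn_pad(X, geom$int_idx, geom$n_padded) else X
  Xcol <- nn_gather(Xp, geom$col_idx)
  dim(Xcol) <- c(geom$k2C, geom$npix * B)
  Y <- par$W %*% Xcol + par$b
  dim(Y) <- c(geom$C_out * geom$npix, B)
  list(out = Y, Xcol = Xcol)
}

conv_backward <- function(geom, par, cache, dY) {
  B <- ncol(dY)
  dim(dY) <- c(geom$C_out, geom$npix * B)
  dW <- tcrossprod(dY, cache$Xcol)
  db <- .rowSums(dY, geom$C_out, geom$npix * B)
  dXcol <- crossprod(par$W, dY) # (k2C) x (npix*B)
  dim(dXcol) <- c(geom$k2C * geom$npix, B)
  dXp <- nn_scatter_add(dXcol, geom$col_idx, geom$n_padded)
  dX <- if (geom$padded) nn_gather(dXp, geom$int_idx) else dXp
  list(dX = dX, grads = list(W = dW, b = db))
}

bn_init <- function(C) {
  list(
    gamma = rep(1, C), beta = numeric(C),
    run_mean = numeric(C), run_var = rep(1, C)
  )
}

# Batch normalization over batch + spatial positions, one (gamma, beta) pair
# per channel (the channel index cycles fastest through the stored layout).
# Fused compiled kernels avoid intermediate allocations; running statistics
# (momentum 0.1) serve evaluation mode.
bn_forward <- function(par, X, C, train = TRUE, eps = 1e-5, momentum = 0.1) {
  if (train) {
    r <- nn_bn_fwd_train(X, C, par$gamma, par$beta, eps)
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * r$mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * r$var
    list(out = r$out, X = X, mu = r$mu, inv = r$inv, par = par)
  } else {
    out <- nn_bn_fwd_eval(X, C, par$gamma, par$beta, par$run_mean, par$run_var, eps)
    list(out = out, X = X, mu = par$run_mean,
         inv = 1 / sqrt(par$run_var + eps), par = par)
  }
}

bn_backward <- function(par, cache, dY, C) {
  r <- nn_bn_bwd(cache$X, dY, C, cache$mu, cache$inv, par$gamma)
  list(dX = r$dX, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

relu_forward <- function(X) list(out = nn_relu_fwd(X))

relu_backward <- function(cache, dY) nn_relu_bwd(cache$out, dY)

# --- Adam over a nested list of numeric parameter tensors -------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.null(g)) {
      # parameters without gradients (e.g. batch-norm running statistics)
      return(list(p = p, m = m, v = v))
    }
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p
        out$m[[nm]] <- r$m
        out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
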