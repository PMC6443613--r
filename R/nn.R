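# Compact neural-network primitives used by the segmentation CNN and the
# convolutional auto-encoder: valid 2D convolution via im2col, 2x2 max
# pooling, dense layers, ReLU, and Adam. Arrays are laid out (H, W, C, N)
# so that matrix reshapes follow R's column-major order. Everything is
# deterministic given the R RNG state at initialization.

# Precompute the im2col gather index for a (H, W, C) input and k x k kernel.
# Row order: (dh fastest, dw, c); column order: output (oh fastest, ow).
build_im2col_idx <- function(H, W, C, k) {
  oh <- H - k + 1L
  ow <- W - k + 1L
  stopifnot(oh >= 1, ow >= 1)
  hh <- rep(seq_len(k), times = k * C)
  ww <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  idx <- outer((cc - 1L) * H * W + (ww - 1L) * H + hh,
               (oj - 1L) * H + (oi - 1L), "+")
  list(idx = idx, oh = oh, ow = ow, H = H, W = W, C = C, k = k)
}

conv_init <- function(k, cin, cout) {
  list(W = matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  nrow = k * k * cin, ncol = cout),
       b = numeric(cout))
}

dense_init <- function(din, dout, sd = NULL) {
  sd <- sd %||% sqrt(2 / din)
  list(W = matrix(stats::rnorm(din * dout, sd = sd), nrow = dout, ncol = din),
       b = numeric(dout))
}

conv_forward <- function(x, par, map) {
  N <- dim(x)[4]
  kkC <- nrow(map$idx)
  L <- ncol(map$idx)
  Xf <- matrix(x, ncol = N)
  cols <- Xf[as.vector(map$idx), , drop = FALSE]
  dim(cols) <- c(kkC, L * N)
  out <- crossprod(par$W, cols) + par$b
  out <- aperm(array(out, c(ncol(par$W), map$oh, map$ow, N)), c(2, 3, 1, 4))
  list(out = out, cols = cols, N = N)
}

conv_backward <- function(dout, par, map, cache) {
  N <- cache$N
  cout <- ncol(par$W)
  L <- ncol(map$idx)
  kkC <- nrow(map$idx)
  dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = cout)
  dW <- cache$cols %*% t(dmat)
  db <- rowSums(dmat)
  dcols <- par$W %*% dmat
  dim(dcols) <- c(kkC, L, N)
  dXf <- matrix(0, map$H * map$W * map$C, N)
  for (r in seq_len(kkC)) {
    ii <- map$idx[r, ]
    dXf[ii, ] <- dXf[ii, ] + dcols[r, , ]
  }
  list(dx = array(dXf, c(map$H, map$W, map$C, N)), dW = dW, db = db)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  oh <- H %/% 2L; ow <- W %/% 2L
  stopifnot(oh >= 1, ow >= 1)
  i1 <- seq(1L, 2L * oh, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * ow, 2L); j2 <- j1 + 1L
  M <- cbind(as.vector(x[i1, j1, , , drop = FALSE]),
             as.vector(x[i2, j1, , , drop = FALSE]),
             as.vector(x[i1, j2, , , drop = FALSE]),
             as.vector(x[i2, j2, , , drop = FALSE]))
  k <- max.col(M, ties.method = "first")
  out <- array(M[cbind(seq_len(nrow(M)), k)], c(oh, ow, C, N))
  # linear input index (within one H x W plane) of each candidate
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  base <- cbind((2L * oi - 1L) + (2L * oj - 2L) * H,
                (2L * oi)      + (2L * oj - 2L) * H,
                (2L * oi - 1L) + (2L * oj - 1L) * H,
                (2L * oi)      + (2L * oj - 1L) * H)
  rows <- seq_len(nrow(M))
  cell <- ((rows - 1L) %% (oh * ow)) + 1L
  plane <- (rows - 1L) %/% (oh * ow)
  lin <- base[cbind(cell, k)] + plane * H * W
  list(out = out, lin = lin, in_dim = d)
}

maxpool_backward <- function(dout, cache) {
  dx <- array(0, cache$in_dim)
  dx[cache$lin] <- as.vector(dout)
  dx
}

dense_forward <- function(x, par) par$W %*% x + par$b

dense_backward <- function(dout, par, x) {
  list(dx = crossprod(par$W, dout), dW = dout %*% t(x), db = rowSums(dout))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(dout, act) {
  dout[act <= 0] <- 0
  dout
}

# Adam over a flat named list of parameter lists (each with $W, $b).
adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (comp in c("W", "b")) {
      g <- grads[[nm]][[paste0("d", comp)]]
      m <- state[[nm]][[paste0("m", comp)]]
      v <- state[[nm]][[paste0("v", comp)]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      params[[nm]][[comp]] <- params[[nm]][[comp]] - lr * mhat / (sqrt(vhat) + eps)
      state[[nm]][[paste0("m", comp)]] <- m
      state[[nm]][[paste0("v", comp)]] <- v
    }
  }
  list(params = params, state = state)
}
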