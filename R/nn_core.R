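# Low-level neural-network primitives.
#
# Activations are 3D arrays with dim (channels, length, batch) so that a
# channel-indexed vector recycles correctly over the flattened (C, L*N)
# matrix view (column-major). Convolutions are evaluated as a single matrix
# product per layer via im2col, which hands the heavy lifting to BLAS.

# --- conv1d ------------------------------------------------------------

# weight layout: W is (C_out, C_in * k), column index (t - 1) * C_in + c
# matching the tap-major im2col below; no bias (a batch norm follows every
# convolution in this architecture).

conv_out_len <- function(l_in, kernel, stride, pad) {
  (l_in + 2L * pad - kernel) %/% stride + 1L
}

conv1d_forward <- function(x, W, stride, pad) {
  .conv1d_forward_cpp(as.numeric(x), dim(x), W, stride, pad)
}

conv1d_backward <- function(dy, cols, W, x_dim, stride, pad, need_dx = TRUE) {
  .conv1d_backward_cpp(as.numeric(dy), cols, W, x_dim, stride, pad, need_dx)
}

# Plain-R reference implementations of the convolution kernels; retained as
# the independent oracle the compiled path is verified against.

im2col <- function(x, kernel, stride, pad) {
  d <- dim(x); C <- d[1]; L <- d[2]; N <- d[3]
  Lp <- L + 2L * pad
  xp <- array(0, c(C, Lp, N))
  xp[, (pad + 1L):(pad + L), ] <- x
  l_out <- conv_out_len(L, kernel, stride, pad)
  cols <- matrix(0, C * kernel, l_out * N)
  for (t in seq_len(kernel)) {
    pos <- seq.int(t, by = stride, length.out = l_out)
    blk <- xp[, pos, , drop = FALSE]
    cols[((t - 1L) * C + 1L):(t * C), ] <- matrix(blk, C)
  }
  cols
}

conv1d_forward_ref <- function(x, W, stride, pad) {
  d <- dim(x); N <- d[3]
  k <- ncol(W) %/% d[1]
  l_out <- conv_out_len(d[2], k, stride, pad)
  cols <- im2col(x, k, stride, pad)
  y <- W %*% cols
  dim(y) <- c(nrow(W), l_out, N)
  list(y = y, cols = cols)
}

conv1d_backward_ref <- function(dy, cols, W, x_dim, stride, pad) {
  C_in <- x_dim[1]; L <- x_dim[2]; N <- x_dim[3]
  k <- ncol(W) %/% C_in
  C_out <- nrow(W)
  dy_m <- matrix(dy, C_out)
  dW <- dy_m %*% t(cols)
  dcols <- crossprod(W, dy_m)
  Lp <- L + 2L * pad
  l_out <- dim(dy)[2]
  dxp <- array(0, c(C_in, Lp, N))
  for (t in seq_len(k)) {
    pos <- seq.int(t, by = stride, length.out = l_out)
    slice <- dcols[((t - 1L) * C_in + 1L):(t * C_in), , drop = FALSE]
    dim(slice) <- c(C_in, l_out, N)
    dxp[, pos, ] <- dxp[, pos, , drop = FALSE] + slice
  }
  dx <- dxp[, (pad + 1L):(pad + L), , drop = FALSE]
  dim(dx) <- c(C_in, L, N)
  list(dW = dW, dx = dx)
}

# --- batch norm --------------------------------------------------------

# Per-channel normalization. In training mode batch statistics are used and
# running statistics updated (momentum 0.1, unbiased variance in the running
# buffer, PyTorch convention). In eval/adaptation mode the supplied fixed
# statistics are used and treated as constants in the backward pass, so only
# the affine parameters receive meaningful gradients there.

bn_forward <- function(x, gamma, beta, mean_use, var_use, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  xhat <- (xm - mean_use) / sqrt(var_use + eps)
  y <- xhat * gamma + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv_sd = 1 / sqrt(var_use + eps))
}

bn_batch_stats <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  m <- rowMeans(xm)
  v <- rowMeans(xm * xm) - m * m
  v[v < 0] <- 0
  list(mean = m, var = v, n = ncol(xm))
}

bn_backward_train <- function(dy, cache, gamma) {
  d <- dim(dy)
  dym <- matrix(dy, d[1])
  xhat <- cache$xhat
  m <- ncol(dym)
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * gamma
  dx <- cache$inv_sd * (dxhat - rowSums(dxhat) / m - xhat * rowSums(dxhat * xhat) / m)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_backward_eval <- function(dy, cache, gamma) {
  d <- dim(dy)
  dym <- matrix(dy, d[1])
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  dx <- dym * gamma * cache$inv_sd
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- activations / head ------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, mask = mask)
}

relu_backward <- function(dy, mask) {
  dy[!mask] <- 0
  dy
}

linear_forward <- function(x_flat, W, b) W %*% x_flat + b

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy on logits (2 x N), labels in {0,1}; returns loss and dlogits
ce_loss_grad <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, 2, n)
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / n, p = p)
}

# mean prediction entropy on logits; dH/dz_c = -p_c (log p_c + H) per column
entropy_loss_grad <- function(logits) {
  p <- softmax_cols(logits)
  lp <- log(pmax(p, 1e-12))
  H <- -colSums(p * lp)
  n <- ncol(logits)
  dlogits <- -p * (sweep(lp, 2, H, "+")) / n
  list(loss = mean(H), dlogits = dlogits, p = p, H = H)
}

# --- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, which_names,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in which_names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
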