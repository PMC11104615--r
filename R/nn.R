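# Minimal neural-network engine for the 1D-convolutional VAE.
#
# Batches are numeric arrays of dimension (B, C, L). Convolutions are
# im2col + matrix multiply; transposed convolutions are the adjoint
# scatter. Every layer has an explicit forward (returning a cache) and
# backward (consuming it); gradients are verified against central finite
# differences in the test suite.

.conv_out_len <- function(L, K = 3L, stride = 2L, pad = 1L)
  (L + 2L * pad - K) %/% stride + 1L

.pad_lr <- function(x, pad) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2], d[3] + 2L * pad))
  xp[, , (pad + 1L):(pad + d[3])] <- x
  xp
}

# W: array (C_in, K, C_out); b: numeric C_out
.conv1d_fwd <- function(x, W, b, stride = 2L, pad = 1L) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  dw <- dim(W); K <- dw[2]; Cout <- dw[3]
  Lout <- .conv_out_len(L, K, stride, pad)
  xp <- .pad_lr(x, pad)
  idx <- outer(seq_len(K), (seq_len(Lout) - 1L) * stride, "+")  # K x Lout
  xc <- xp[, , as.vector(idx), drop = FALSE]
  dim(xc) <- c(B, C, K, Lout)
  xc <- aperm(xc, c(1, 4, 2, 3))
  dim(xc) <- c(B * Lout, C * K)
  y <- xc %*% matrix(W, C * K, Cout)
  y <- sweep(y, 2, b, "+")
  dim(y) <- c(B, Lout, Cout)
  list(y = aperm(y, c(1, 3, 2)),
       cache = list(xcol = xc, idx = idx, B = B, C = C, L = L, K = K,
                    Cout = Cout, Lout = Lout, stride = stride, pad = pad))
}

.conv1d_bwd <- function(dy, W, cache) {
  ch <- cache
  dym <- aperm(dy, c(1, 3, 2))
  dim(dym) <- c(ch$B * ch$Lout, ch$Cout)
  dW <- crossprod(ch$xcol, dym)
  dim(dW) <- c(ch$C, ch$K, ch$Cout)
  db <- colSums(dym)
  dxc <- dym %*% t(matrix(W, ch$C * ch$K, ch$Cout))
  dim(dxc) <- c(ch$B, ch$Lout, ch$C, ch$K)
  dxc <- aperm(dxc, c(1, 3, 4, 2))                    # B, C, K, Lout
  dxp <- array(0, c(ch$B, ch$C, ch$L + 2L * ch$pad))
  for (k in seq_len(ch$K)) {
    pos <- ch$idx[k, ]
    dxp[, , pos] <- dxp[, , pos] + dxc[, , k, ]
  }
  list(dx = dxp[, , (ch$pad + 1L):(ch$pad + ch$L), drop = FALSE],
       dW = dW, db = db)
}

# W: array (C_in, C_out, K). out_len must satisfy pad + out_len <= full
# support length (the trailing gap is the output padding).
.tconv1d_fwd <- function(x, W, b, out_len, stride = 2L, pad = 1L) {
  d <- dim(x); B <- d[1]; Cin <- d[2]; Lin <- d[3]
  dw <- dim(W); Cout <- dw[2]; K <- dw[3]
  full <- (Lin - 1L) * stride + K
  stopifnot(pad + out_len <= full)
  xm <- aperm(x, c(1, 3, 2))
  dim(xm) <- c(B * Lin, Cin)
  contrib <- xm %*% matrix(W, Cin, Cout * K)
  dim(contrib) <- c(B, Lin, Cout, K)
  contrib <- aperm(contrib, c(1, 3, 4, 2))            # B, Cout, K, Lin
  yf <- array(0, c(B, Cout, full))
  base <- (seq_len(Lin) - 1L) * stride
  for (k in seq_len(K)) {
    pos <- base + k
    yf[, , pos] <- yf[, , pos] + contrib[, , k, ]
  }
  y <- yf[, , (pad + 1L):(pad + out_len), drop = FALSE]
  y <- sweep(y, 2, b, "+")
  list(y = y,
       cache = list(xm = xm, B = B, Cin = Cin, Lin = Lin, K = K,
                    Cout = Cout, full = full, out_len = out_len,
                    stride = stride, pad = pad))
}

.tconv1d_bwd <- function(dy, W, cache) {
  ch <- cache
  dyf <- array(0, c(ch$B, ch$Cout, ch$full))
  dyf[, , (ch$pad + 1L):(ch$pad + ch$out_len)] <- dy
  base <- (seq_len(ch$Lin) - 1L) * ch$stride
  dcon <- array(0, c(ch$B, ch$Cout, ch$K, ch$Lin))
  for (k in seq_len(ch$K)) dcon[, , k, ] <- dyf[, , base + k]
  dcon <- aperm(dcon, c(1, 4, 2, 3))                  # B, Lin, Cout, K
  dim(dcon) <- c(ch$B * ch$Lin, ch$Cout * ch$K)
  Wm <- matrix(W, ch$Cin, ch$Cout * ch$K)
  dxm <- dcon %*% t(Wm)
  dim(dxm) <- c(ch$B, ch$Lin, ch$Cin)
  dW <- crossprod(ch$xm, dcon)
  dim(dW) <- c(ch$Cin, ch$Cout, ch$K)
  db <- apply(dy, 2, sum)
  list(dx = aperm(dxm, c(1, 3, 2)), dW = dW, db = db)
}

# Batch normalization over (B, C, L): statistics per channel across batch
# and time. Training mode uses batch statistics and updates running
# buffers; evaluation mode uses the running buffers (deterministic).
.bn_fwd <- function(x, gamma, beta, rm, rv, training, momentum = 0.1,
                    eps = 1e-5) {
  if (training) {
    m <- apply(x, 2, mean)
    xc <- sweep(x, 2, m)
    v <- apply(xc * xc, 2, mean)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv, "*")
    N <- dim(x)[1] * dim(x)[3]
    corr <- if (N > 1L) N / (N - 1L) else 1
    rm_new <- (1 - momentum) * rm + momentum * m
    rv_new <- (1 - momentum) * rv + momentum * v * corr
  } else {
    inv <- 1 / sqrt(rv + eps)
    xhat <- sweep(sweep(x, 2, rm), 2, inv, "*")
    rm_new <- rm; rv_new <- rv
  }
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, rm = rm_new, rv = rv_new,
       cache = list(xhat = xhat, inv = inv, gamma = gamma,
                    training = training))
}

.bn_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  N <- dim(dy)[1] * dim(dy)[3]
  dgamma <- apply(dy * xhat, 2, sum)
  dbeta <- apply(dy, 2, sum)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  if (cache$training) {
    s1 <- apply(dxhat, 2, sum)
    s2 <- apply(dxhat * xhat, 2, sum)
    dx <- sweep(dxhat, 2, s1 / N) - sweep(xhat, 2, s2 / N, "*")
    dx <- sweep(dx, 2, inv, "*")
  } else {
    dx <- sweep(dxhat, 2, inv, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.linear_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- sweep(y, 2, b, "+")
  list(y = y, cache = x)
}

.linear_bwd <- function(dy, W, cache)
  list(dx = dy %*% t(W), dW = crossprod(cache, dy), db = colSums(dy))

.tanh_fwd <- function(x) { y <- tanh(x); list(y = y, cache = y) }
.tanh_bwd <- function(dy, cache) dy * (1 - cache * cache)

# PyTorch-style uniform init: U(-1/sqrt(fan_in), 1/sqrt(fan_in)).
.init_mat <- function(fan_in, dims) {
  bound <- 1 / sqrt(fan_in)
  array(runif(prod(dims), -bound, bound), dims)
}

.adam_init <- function(params)
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
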