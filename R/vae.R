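#' Architecture of the convolutional VAE
#'
#' The encoder applies three 1D convolutions (kernel 3, stride 2, padding
#' 1) with channels (3,4), (4,8), (8,16), batch normalization after each,
#' and tanh activations; the flattened features (16 x 94 = 1504 for a
#' 750-point input) pass through a fully connected layer (1504, 256) and
#' two fully connected heads (256, 128), (128, 32) producing the latent
#' mean and log-variance (final head layers linear). The decoder mirrors
#' it: fully connected (32, 128), (128, 256), (256, 1504), reshape to
#' (B, 16, 94), then three transposed convolutions (kernel 3, stride 2,
#' padding 1) whose output paddings are computed so the temporal lengths
#' return 94 -> 188 -> 375 -> 750; the final layer is linear.
#'
#' @param input_length trace length (default 750).
#' @param channels input channels (default 3).
#' @param latent_dim latent dimension (default 32).
#' @return list describing the architecture, including the per-stage
#'   temporal \code{lengths}, the flattened width \code{flat}, and the
#'   transposed-convolution output paddings \code{out_pads}.
#' @examples
#' architectureSpec()$flat      # 1504
#' architectureSpec()$lengths   # 750 375 188 94
#' @export
architectureSpec <- function(input_length = 750L, channels = 3L,
                             latent_dim = 32L) {
  L0 <- as.integer(input_length)
  L1 <- .conv_out_len(L0); L2 <- .conv_out_len(L1); L3 <- .conv_out_len(L2)
  conv_ch <- c(channels, 4L, 8L, 16L)
  flat <- conv_ch[4] * L3
  targets <- c(L2, L1, L0)
  ins <- c(L3, L2, L1)
  out_pads <- targets - ((ins - 1L) * 2L - 2L + 3L)
  if (any(out_pads < 0L | out_pads > 1L))
    stop("input_length incompatible with the stride-2 architecture")
  list(input_length = L0, channels = as.integer(channels),
       latent_dim = as.integer(latent_dim), conv_channels = conv_ch,
       lengths = c(L0, L1, L2, L3), flat = flat, fc_width = 256L,
       head_hidden = 128L, dec_channels = rev(conv_ch),
       dec_lengths = targets, out_pads = out_pads)
}

.vae_init <- function(arch) {
  cc <- arch$conv_channels; K <- 3L
  p <- list(
    ec1W = .init_mat(cc[1] * K, c(cc[1], K, cc[2])), ec1b = rep(0, cc[2]),
    ebn1g = rep(1, cc[2]), ebn1b = rep(0, cc[2]),
    ec2W = .init_mat(cc[2] * K, c(cc[2], K, cc[3])), ec2b = rep(0, cc[3]),
    ebn2g = rep(1, cc[3]), ebn2b = rep(0, cc[3]),
    ec3W = .init_mat(cc[3] * K, c(cc[3], K, cc[4])), ec3b = rep(0, cc[4]),
    ebn3g = rep(1, cc[4]), ebn3b = rep(0, cc[4]),
    efW = .init_mat(arch$flat, c(arch$flat, arch$fc_width)),
    efb = rep(0, arch$fc_width),
    em1W = .init_mat(arch$fc_width, c(arch$fc_width, arch$head_hidden)),
    em1b = rep(0, arch$head_hidden),
    em2W = .init_mat(arch$head_hidden, c(arch$head_hidden, arch$latent_dim)),
    em2b = rep(0, arch$latent_dim),
    ev1W = .init_mat(arch$fc_width, c(arch$fc_width, arch$head_hidden)),
    ev1b = rep(0, arch$head_hidden),
    ev2W = .init_mat(arch$head_hidden, c(arch$head_hidden, arch$latent_dim)),
    ev2b = rep(0, arch$latent_dim),
    df1W = .init_mat(arch$latent_dim, c(arch$latent_dim, arch$head_hidden)),
    df1b = rep(0, arch$head_hidden),
    df2W = .init_mat(arch$head_hidden, c(arch$head_hidden, arch$fc_width)),
    df2b = rep(0, arch$fc_width),
    df3W = .init_mat(arch$fc_width, c(arch$fc_width, arch$flat)),
    df3b = rep(0, arch$flat),
    dt1W = .init_mat(cc[4] * K, c(cc[4], cc[3], K)), dt1b = rep(0, cc[3]),
    dbn1g = rep(1, cc[3]), dbn1b = rep(0, cc[3]),
    dt2W = .init_mat(cc[3] * K, c(cc[3], cc[2], K)), dt2b = rep(0, cc[2]),
    dbn2g = rep(1, cc[2]), dbn2b = rep(0, cc[2]),
    dt3W = .init_mat(cc[2] * K, c(cc[2], cc[1], K)), dt3b = rep(0, cc[1]))
  buf <- list(
    ebn1m = rep(0, cc[2]), ebn1v = rep(1, cc[2]),
    ebn2m = rep(0, cc[3]), ebn2v = rep(1, cc[3]),
    ebn3m = rep(0, cc[4]), ebn3v = rep(1, cc[4]),
    dbn1m = rep(0, cc[3]), dbn1v = rep(1, cc[3]),
    dbn2m = rep(0, cc[2]), dbn2v = rep(1, cc[2]))
  list(params = p, buffers = buf)
}

.enc_fwd <- function(p, buf, x, training) {
  B <- dim(x)[1]
  c1 <- .conv1d_fwd(x, p$ec1W, p$ec1b)
  b1 <- .bn_fwd(c1$y, p$ebn1g, p$ebn1b, buf$ebn1m, buf$ebn1v, training)
  a1 <- .tanh_fwd(b1$y)
  c2 <- .conv1d_fwd(a1$y, p$ec2W, p$ec2b)
  b2 <- .bn_fwd(c2$y, p$ebn2g, p$ebn2b, buf$ebn2m, buf$ebn2v, training)
  a2 <- .tanh_fwd(b2$y)
  c3 <- .conv1d_fwd(a2$y, p$ec3W, p$ec3b)
  b3 <- .bn_fwd(c3$y, p$ebn3g, p$ebn3b, buf$ebn3m, buf$ebn3v, training)
  a3 <- .tanh_fwd(b3$y)
  h <- a3$y
  dim(h) <- c(B, prod(dim(a3$y)[2:3]))      # feature = (channel, time) pairs
  f <- .linear_fwd(h, p$efW, p$efb)
  af <- .tanh_fwd(f$y)
  m1 <- .linear_fwd(af$y, p$em1W, p$em1b)
  am <- .tanh_fwd(m1$y)
  m2 <- .linear_fwd(am$y, p$em2W, p$em2b)
  v1 <- .linear_fwd(af$y, p$ev1W, p$ev1b)
  av <- .tanh_fwd(v1$y)
  v2 <- .linear_fwd(av$y, p$ev2W, p$ev2b)
  if (training) {
    buf$ebn1m <- b1$rm; buf$ebn1v <- b1$rv
    buf$ebn2m <- b2$rm; buf$ebn2v <- b2$rv
    buf$ebn3m <- b3$rm; buf$ebn3v <- b3$rv
  }
  list(mu = m2$y, logvar = v2$y, buffers = buf,
       cache = list(c1 = c1, b1 = b1, a1 = a1, c2 = c2, b2 = b2, a2 = a2,
                    c3 = c3, b3 = b3, a3 = a3, f = f, af = af, m1 = m1,
                    am = am, m2 = m2, v1 = v1, av = av, v2 = v2,
                    hdim = dim(a3$y)))
}

.enc_bwd <- function(p, dmu, dlogvar, cc) {
  g <- list()
  lm2 <- .linear_bwd(dmu, p$em2W, cc$m2$cache)
  g$em2W <- lm2$dW; g$em2b <- lm2$db
  dam <- .tanh_bwd(lm2$dx, cc$am$cache)
  lm1 <- .linear_bwd(dam, p$em1W, cc$m1$cache)
  g$em1W <- lm1$dW; g$em1b <- lm1$db
  lv2 <- .linear_bwd(dlogvar, p$ev2W, cc$v2$cache)
  g$ev2W <- lv2$dW; g$ev2b <- lv2$db
  dav <- .tanh_bwd(lv2$dx, cc$av$cache)
  lv1 <- .linear_bwd(dav, p$ev1W, cc$v1$cache)
  g$ev1W <- lv1$dW; g$ev1b <- lv1$db
  daf <- .tanh_bwd(lm1$dx + lv1$dx, cc$af$cache)
  lf <- .linear_bwd(daf, p$efW, cc$f$cache)
  g$efW <- lf$dW; g$efb <- lf$db
  dh <- lf$dx
  dim(dh) <- cc$hdim
  da3 <- .tanh_bwd(dh, cc$a3$cache)
  bb3 <- .bn_bwd(da3, cc$b3$cache)
  g$ebn3g <- bb3$dgamma; g$ebn3b <- bb3$dbeta
  cb3 <- .conv1d_bwd(bb3$dx, p$ec3W, cc$c3$cache)
  g$ec3W <- cb3$dW; g$ec3b <- cb3$db
  da2 <- .tanh_bwd(cb3$dx, cc$a2$cache)
  bb2 <- .bn_bwd(da2, cc$b2$cache)
  g$ebn2g <- bb2$dgamma; g$ebn2b <- bb2$dbeta
  cb2 <- .conv1d_bwd(bb2$dx, p$ec2W, cc$c2$cache)
  g$ec2W <- cb2$dW; g$ec2b <- cb2$db
  da1 <- .tanh_bwd(cb2$dx, cc$a1$cache)
  bb1 <- .bn_bwd(da1, cc$b1$cache)
  g$ebn1g <- bb1$dgamma; g$ebn1b <- bb1$dbeta
  cb1 <- .conv1d_bwd(bb1$dx, p$ec1W, cc$c1$cache)
  g$ec1W <- cb1$dW; g$ec1b <- cb1$db
  g
}

.dec_fwd <- function(p, buf, z, arch, training) {
  B <- nrow(z)
  f1 <- .linear_fwd(z, p$df1W, p$df1b); a1 <- .tanh_fwd(f1$y)
  f2 <- .linear_fwd(a1$y, p$df2W, p$df2b); a2 <- .tanh_fwd(f2$y)
  f3 <- .linear_fwd(a2$y, p$df3W, p$df3b); a3 <- .tanh_fwd(f3$y)
  h <- a3$y
  dim(h) <- c(B, arch$conv_channels[4], arch$lengths[4])
  t1 <- .tconv1d_fwd(h, p$dt1W, p$dt1b, arch$dec_lengths[1])
  b1 <- .bn_fwd(t1$y, p$dbn1g, p$dbn1b, buf$dbn1m, buf$dbn1v, training)
  u1 <- .tanh_fwd(b1$y)
  t2 <- .tconv1d_fwd(u1$y, p$dt2W, p$dt2b, arch$dec_lengths[2])
  b2 <- .bn_fwd(t2$y, p$dbn2g, p$dbn2b, buf$dbn2m, buf$dbn2v, training)
  u2 <- .tanh_fwd(b2$y)
  t3 <- .tconv1d_fwd(u2$y, p$dt3W, p$dt3b, arch$dec_lengths[3])
  if (training) {
    buf$dbn1m <- b1$rm; buf$dbn1v <- b1$rv
    buf$dbn2m <- b2$rm; buf$dbn2v <- b2$rv
  }
  list(xhat = t3$y, buffers = buf,
       cache = list(f1 = f1, a1 = a1, f2 = f2, a2 = a2, f3 = f3, a3 = a3,
                    t1 = t1, b1 = b1, u1 = u1, t2 = t2, b2 = b2, u2 = u2,
                    t3 = t3, B = B))
}

.dec_bwd <- function(p, dxhat, cc) {
  g <- list()
  tb3 <- .tconv1d_bwd(dxhat, p$dt3W, cc$t3$cache)
  g$dt3W <- tb3$dW; g$dt3b <- tb3$db
  du2 <- .tanh_bwd(tb3$dx, cc$u2$cache)
  bb2 <- .bn_bwd(du2, cc$b2$cache)
  g$dbn2g <- bb2$dgamma; g$dbn2b <- bb2$dbeta
  tb2 <- .tconv1d_bwd(bb2$dx, p$dt2W, cc$t2$cache)
  g$dt2W <- tb2$dW; g$dt2b <- tb2$db
  du1 <- .tanh_bwd(tb2$dx, cc$u1$cache)
  bb1 <- .bn_bwd(du1, cc$b1$cache)
  g$dbn1g <- bb1$dgamma; g$dbn1b <- bb1$dbeta
  tb1 <- .tconv1d_bwd(bb1$dx, p$dt1W, cc$t1$cache)
  g$dt1W <- tb1$dW; g$dt1b <- tb1$db
  dh <- tb1$dx
  dim(dh) <- c(cc$B, prod(dim(tb1$dx)[2:3]))
  da3 <- .tanh_bwd(dh, cc$a3$cache)
  lf3 <- .linear_bwd(da3, p$df3W, cc$f3$cache)
  g$df3W <- lf3$dW; g$df3b <- lf3$db
  da2 <- .tanh_bwd(lf3$dx, cc$a2$cache)
  lf2 <- .linear_bwd(da2, p$df2W, cc$f2$cache)
  g$df2W <- lf2$dW; g$df2b <- lf2$db
  da1 <- .tanh_bwd(lf2$dx, cc$a1$cache)
  lf1 <- .linear_bwd(da1, p$df1W, cc$f1$cache)
  g$df1W <- lf1$dW; g$df1b <- lf1$db
  list(dz = lf1$dx, grads = g)
}

# One forward/backward pass. Loss is the per-sample mean of
# sum-of-squares reconstruction error plus KL to the unit-Gaussian prior.
.vae_step <- function(p, buf, arch, x_in, x_target, eps_z) {
  B <- dim(x_in)[1]
  enc <- .enc_fwd(p, buf, x_in, training = TRUE)
  logvar <- enc$logvar
  sdv <- exp(0.5 * logvar)
  z <- enc$mu + sdv * eps_z
  dec <- .dec_fwd(p, enc$buffers, z, arch, training = TRUE)
  diff <- dec$xhat - x_target
  recon <- sum(diff * diff)
  varv <- sdv * sdv
  kl <- 0.5 * sum(varv + enc$mu^2 - 1 - logvar)
  dxhat <- 2 * diff / B
  db <- .dec_bwd(p, dxhat, dec$cache)
  dmu <- db$dz + enc$mu / B
  dlogvar <- db$dz * (0.5 * sdv * eps_z) + 0.5 * (varv - 1) / B
  ge <- .enc_bwd(p, dmu, dlogvar, enc$cache)
  list(grads = c(ge, db$grads), buffers = dec$buffers,
       recon = recon / B, kl = kl / B, total = (recon + kl) / B)
}

#' Training configuration
#'
#' Standard settings: Adam with learning rate 0.001, batch size 32, an
#' 80/20 train/validation split, unit-Gaussian input noise of variance
#' 0.01 (sd 0.1) injected into training inputs only (reconstruction
#' targets stay clean), and a fixed epoch budget of at most 100 with no
#' early stopping.
#'
#' @param epochs number of epochs (<= 100).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 0.001).
#' @param train_frac training fraction (default 0.8).
#' @param noise_sd sd of input noise injected during training (default 0.1).
#' @param seed integer seed controlling initialization, split, shuffling,
#'   noise and latent sampling.
#' @return validated configuration list.
#' @export
trainConfig <- function(epochs = 30L, batch_size = 32L, lr = 1e-3,
                        train_frac = 0.8, noise_sd = 0.1, seed = 1L) {
  stopifnot(epochs >= 1L, epochs <= 100L, batch_size >= 1L, lr > 0,
            train_frac > 0, train_frac < 1, noise_sd >= 0)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, train_frac = train_frac, noise_sd = noise_sd,
       seed = as.integer(seed))
}

.eval_losses <- function(p, buf, arch, x, chunk = 256L) {
  n <- dim(x)[1]
  recon <- 0; kl <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xb <- x[s:e, , , drop = FALSE]
    enc <- .enc_fwd(p, buf, xb, training = FALSE)
    dec <- .dec_fwd(p, buf, enc$mu, arch, training = FALSE)
    recon <- recon + sum((dec$xhat - xb)^2)
    varv <- exp(enc$logvar)
    kl <- kl + 0.5 * sum(varv + enc$mu^2 - 1 - enc$logvar)
  }
  c(recon = recon / n, kl = kl / n, total = (recon + kl) / n)
}

#' Train the variational autoencoder
#'
#' Trains the 1D-convolutional VAE on a \linkS4class{TraceMatrix} by
#' minimizing the negative evidence lower bound: per-sample sum-of-squares
#' reconstruction error (Gaussian decoder likelihood with fixed unit
#' variance) plus the closed-form KL divergence of the diagonal-Gaussian
#' posterior to the unit-Gaussian prior, using the reparameterization
#' trick. Training inputs are perturbed with N(0, 0.01) noise; targets
#' stay clean. Validation losses are computed each epoch on clean inputs
#' in evaluation mode with the deterministic latent z = mu.
#'
#' @param tm a \linkS4class{TraceMatrix} with at least 2 cells.
#' @param arch an \code{\link{architectureSpec}}.
#' @param config a \code{\link{trainConfig}}.
#' @param verbose print per-epoch losses.
#' @return a \linkS4class{TrainedVAE}.
#' @export
trainVAE <- function(tm, arch = architectureSpec(), config = trainConfig(),
                     verbose = FALSE) {
  x <- traceArray(tm)
  n <- dim(x)[1]
  if (n < 2L) stop("need at least 2 cells to train")
  if (dim(x)[2] != arch$channels || dim(x)[3] != arch$input_length)
    stop("trace matrix does not match the architecture input shape")
  set.seed(config$seed)
  init <- .vae_init(arch)
  p <- init$params; buf <- init$buffers
  opt <- .adam_init(p)
  perm0 <- sample(n)
  ntr <- max(1L, floor(config$train_frac * n))
  tr_idx <- perm0[seq_len(ntr)]
  va_idx <- if (ntr < n) perm0[(ntr + 1L):n] else tr_idx
  xv <- x[va_idx, , , drop = FALSE]
  d <- arch$latent_dim
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    starts <- seq(1L, length(ord), by = config$batch_size)
    tr_recon <- 0; tr_kl <- 0
    for (s in starts) {
      b <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      xb <- x[b, , , drop = FALSE]
      B <- length(b)
      x_in <- if (config$noise_sd > 0)
        xb + array(rnorm(length(xb), 0, config$noise_sd), dim(xb)) else xb
      eps_z <- matrix(rnorm(B * d), B, d)
      st <- .vae_step(p, buf, arch, x_in, xb, eps_z)
      buf <- st$buffers
      upd <- .adam_step(p, st$grads, opt, lr = config$lr)
      p <- upd$params; opt <- upd$state
      tr_recon <- tr_recon + st$recon * B
      tr_kl <- tr_kl + st$kl * B
    }
    vl <- .eval_losses(p, buf, arch, xv)
    hist[[ep]] <- data.frame(
      epoch = ep,
      train_recon = tr_recon / length(ord), train_kl = tr_kl / length(ord),
      train_total = (tr_recon + tr_kl) / length(ord),
      val_recon = vl[["recon"]], val_kl = vl[["kl"]],
      val_total = vl[["total"]])
    if (verbose)
      message(sprintf("epoch %3d  train %.2f  val %.2f", ep,
                      hist[[ep]]$train_total, hist[[ep]]$val_total))
  }
  methods::new("TrainedVAE", params = p, buffers = buf, arch = arch,
               config = c(config, list(train_idx = tr_idx, val_idx = va_idx)),
               history = do.call(rbind, hist))
}

#' Encode traces to latent diagonal Gaussians
#'
#' Runs the encoder in evaluation mode (deterministic: batch-norm running
#' statistics, no sampling).
#'
#' @param vae a \linkS4class{TrainedVAE}.
#' @param x numeric array, cells x 3 x 750 (or a
#'   \linkS4class{TraceMatrix}).
#' @param chunk internal batch size for memory control.
#' @return \code{list(mu, var)} matrices, cells x latent dim; var > 0.
#' @export
vaeEncode <- function(vae, x, chunk = 256L) {
  if (methods::is(x, "TraceMatrix")) x <- traceArray(x)
  if (length(dim(x)) != 3L || dim(x)[2] != vae@arch$channels ||
      dim(x)[3] != vae@arch$input_length)
    stop("input must be cells x ", vae@arch$channels, " x ",
         vae@arch$input_length)
  n <- dim(x)[1]
  d <- vae@arch$latent_dim
  mu <- matrix(0, n, d); va <- matrix(0, n, d)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    enc <- .enc_fwd(vae@params, vae@buffers, x[s:e, , , drop = FALSE],
                    training = FALSE)
    mu[s:e, ] <- enc$mu
    va[s:e, ] <- exp(enc$logvar)
  }
  list(mu = mu, var = va)
}

#' Decode latent vectors to traces
#'
#' Runs the decoder in evaluation mode. The intermediate reshape has 16
#' channels of temporal length 94; the three transposed convolutions
#' restore length 750.
#'
#' @param vae a \linkS4class{TrainedVAE}.
#' @param z numeric matrix, n x latent dim (a single vector is accepted).
#' @param chunk internal batch size.
#' @return numeric array, n x 3 x 750.
#' @export
vaeDecode <- function(vae, z, chunk = 256L) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != vae@arch$latent_dim)
    stop("latent dimension must be ", vae@arch$latent_dim)
  n <- nrow(z)
  out <- array(0, c(n, vae@arch$channels, vae@arch$input_length))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dec <- .dec_fwd(vae@params, vae@buffers, z[s:e, , drop = FALSE],
                    vae@arch, training = FALSE)
    out[s:e, , ] <- dec$xhat
  }
  out
}

#' Reparameterized sample from a diagonal Gaussian posterior
#'
#' z = mu + sqrt(var) * eps with eps standard normal, so a sample is a
#' differentiable function of (mu, var).
#'
#' @param mu,var numeric vectors (or matrices, sampled row-wise).
#' @return sample(s) with the same shape as \code{mu}.
#' @export
sampleLatent <- function(mu, var) {
  if (any(var <= 0)) stop("var must be strictly positive")
  eps <- rnorm(length(mu))
  if (!is.null(dim(mu))) dim(eps) <- dim(mu)
  mu + sqrt(var) * eps
}

#' KL divergence of a diagonal Gaussian to the unit-Gaussian prior
#'
#' Closed form: 0.5 * sum(var + mu^2 - 1 - log(var)), in nats;
#' non-negative, zero iff mu = 0 and var = 1.
#'
#' @param mu,var numeric vectors, or matrices for per-row divergences.
#' @return scalar (vector input) or per-row numeric vector (matrix input).
#' @examples
#' klToPrior(1, 1)  # 0.5
#' @export
klToPrior <- function(mu, var) {
  if (any(var <= 0)) stop("var must be strictly positive")
  term <- var + mu^2 - 1 - log(var)
  if (is.matrix(mu)) 0.5 * rowSums(term) else 0.5 * sum(term)
}

#' ELBO loss components
#'
#' Reconstruction term is the sum of squared errors over channels, time
#' and batch (Gaussian decoder with fixed unit variance, constants
#' dropped); the KL term is \code{\link{klToPrior}} summed over the batch;
#' total = recon + kl is the minimized objective.
#'
#' @param x,x_hat equal-shaped numeric arrays.
#' @param mu,var latent posterior parameters (matrix, cells x d).
#' @return \code{list(recon, kl, total)}.
#' @export
elboLoss <- function(x, x_hat, mu, var) {
  if (!identical(dim(x), dim(x_hat)))
    stop("x and x_hat must have identical shapes")
  recon <- sum((x - x_hat)^2)
  kl <- sum(klToPrior(mu, var))
  list(recon = recon, kl = kl, total = recon + kl)
}

#' Embed all cells of a trace matrix as latent posteriors
#'
#' @param vae a \linkS4class{TrainedVAE}.
#' @param tm a \linkS4class{TraceMatrix}.
#' @return a \linkS4class{LatentTable} aligned with the cells of \code{tm}.
#' @export
embedCells <- function(vae, tm) {
  enc <- vaeEncode(vae, tm)
  LatentTable(enc$mu, enc$var, cellData = SummarizedExperiment::colData(tm))
}
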