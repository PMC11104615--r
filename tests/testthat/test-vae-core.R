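test_that("architecture arithmetic matches the stride-2 design", {
  arch <- architectureSpec()
  expect_identical(arch$lengths, c(750L, 375L, 188L, 94L))
  expect_identical(arch$flat, 1504L)
  # transposed convolutions restore 94 -> 188 -> 375 -> 750
  expect_identical(arch$dec_lengths, c(188L, 375L, 750L))
  expect_identical(arch$out_pads, c(1L, 0L, 1L))
})

test_that("encode/decode have the contracted shapes and are deterministic", {
  arch <- architectureSpec()
  set.seed(1)
  init <- TraceVAE:::.vae_init(arch)
  vae <- new("TrainedVAE", params = init$params, buffers = init$buffers,
             arch = arch, config = trainConfig(), history = data.frame())
  x <- array(runif(5 * 3 * 750), c(5, 3, 750))
  enc <- vaeEncode(vae, x)
  expect_identical(dim(enc$mu), c(5L, 32L))
  expect_identical(dim(enc$var), c(5L, 32L))
  expect_true(all(enc$var > 0))
  enc2 <- vaeEncode(vae, x)
  expect_identical(enc, enc2)
  # identical traces -> identical latents
  x2 <- x; x2[2, , ] <- x2[1, , ]
  e <- vaeEncode(vae, x2)
  expect_equal(e$mu[1, ], e$mu[2, ], tolerance = 1e-12)
  expect_error(vaeEncode(vae, array(0, c(2, 3, 700))), "must be cells x")
  # decode shapes, including a zero latent vector, for random parameters
  z <- rbind(rep(0, 32), matrix(rnorm(3 * 32), 3, 32))
  out <- vaeDecode(vae, z)
  expect_identical(dim(out), c(4L, 3L, 750L))
  expect_true(all(is.finite(out)))
  expect_error(vaeDecode(vae, matrix(0, 1, 16)), "latent dimension")
})

test_that("reparameterized sampling has the right moments", {
  mu <- c(1, -2, 0.5); va <- c(0.2, 1, 4)
  expect_equal(sampleLatent(mu, va * 0 + 1e-30), mu, tolerance = 1e-6)
  set.seed(8)
  zs <- matrix(0, 1e5, 3)
  z <- sampleLatent(matrix(mu, 1e5, 3, byrow = TRUE),
                    matrix(va, 1e5, 3, byrow = TRUE))
  expect_true(all(abs(colMeans(z) - mu) < 3 * sqrt(va / 1e5)))
  set.seed(3); a <- sampleLatent(mu, va)
  set.seed(3); b <- sampleLatent(mu, va)
  expect_identical(a, b)
})

test_that("KL to the unit-Gaussian prior matches closed form and Monte Carlo", {
  expect_equal(klToPrior(rep(0, 32), rep(1, 32)), 0)
  expect_equal(klToPrior(1, 1), 0.5)
  expect_error(klToPrior(0, -1), "positive")
  # Monte-Carlo oracle at d = 4
  set.seed(21)
  mu <- rnorm(4); va <- exp(rnorm(4, 0, 0.5))
  n <- 1e6
  z <- matrix(rnorm(n * 4), n, 4)
  z <- sweep(sweep(z, 2, sqrt(va), "*"), 2, mu, "+")
  lq <- -0.5 * rowSums(sweep(sweep(z, 2, mu)^2, 2, va, "/") +
                         matrix(log(2 * pi * va), n, 4, byrow = TRUE))
  lp <- -0.5 * rowSums(z^2 + log(2 * pi))
  mc <- lq - lp
  expect_lt(abs(klToPrior(mu, va) - mean(mc)), 3 * sd(mc) / sqrt(n))
  # agrees with the generic diagonal-Gaussian KL against the prior
  expect_equal(klToPrior(mu, va),
               klDiagGauss(mu, va, rep(0, 4), rep(1, 4)), tolerance = 1e-10)
})

test_that("ELBO components are additive and quadratic in the residual", {
  x <- array(runif(2 * 3 * 750), c(2, 3, 750))
  mu <- matrix(rnorm(2 * 32), 2); va <- matrix(exp(rnorm(2 * 32)), 2)
  l0 <- elboLoss(x, x, matrix(0, 2, 32), matrix(1, 2, 32))
  expect_equal(l0$total, 0)
  xh <- x + 0.1
  l1 <- elboLoss(x, xh, mu, va)
  l2 <- elboLoss(x, x + 0.2, mu, va)
  expect_equal(l2$recon, 4 * l1$recon, tolerance = 1e-10)
  expect_equal(l1$total, l1$recon + l1$kl)
  expect_error(elboLoss(x, x[1, , , drop = FALSE], mu, va), "identical shapes")
})

test_that("analytic gradients match finite differences through the full model", {
  arch <- architectureSpec()
  set.seed(33)
  init <- TraceVAE:::.vae_init(arch)
  p <- init$params; buf <- init$buffers
  B <- 2L
  x <- array(runif(B * 3 * 750), c(B, 3, 750))
  eps_z <- matrix(rnorm(B * 32), B, 32)
  loss_fn <- function(p) {
    enc <- TraceVAE:::.enc_fwd(p, buf, x, training = TRUE)
    sdv <- exp(0.5 * enc$logvar)
    z <- enc$mu + sdv * eps_z
    dec <- TraceVAE:::.dec_fwd(p, enc$buffers, z, arch, training = TRUE)
    (sum((dec$xhat - x)^2) +
       0.5 * sum(sdv^2 + enc$mu^2 - 1 - enc$logvar)) / B
  }
  st <- TraceVAE:::.vae_step(p, buf, arch, x, x, eps_z)
  # probe two random coordinates in every parameter tensor
  set.seed(34)
  for (nm in names(st$grads)) {
    for (i in sample(length(p[[nm]]), min(2L, length(p[[nm]])))) {
      h <- 1e-5 * max(1, abs(p[[nm]][i]))
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
      g <- st$grads[[nm]][i]
      # relative error with an absolute floor (a conv bias followed by
      # batch norm has an exactly-zero gradient; finite differences only
      # see cancellation noise there)
      expect_lt(abs(num - g), 1e-4 * max(1, abs(num), abs(g)))
    }
  }
})

test_that("training runs, records finite history, and is seed-reproducible", {
  cfg <- generatorConfig(n_cells = 64, phenotypes = c("cluster_01", "cluster_10"),
                         weights = c(0.5, 0.5), seed = 9)
  tm <- assembleDataset(simulateDataset(cfg))
  v1 <- trainVAE(tm, config = trainConfig(epochs = 2, seed = 4))
  h <- trainingHistory(v1)
  expect_identical(nrow(h), 2L)
  expect_true(all(is.finite(as.matrix(h))))
  v2 <- trainVAE(tm, config = trainConfig(epochs = 2, seed = 4))
  expect_equal(trainingHistory(v2), h, tolerance = 1e-12)
  # embedding aligns with cells and is repeatable
  lt <- embedCells(v1, tm)
  expect_identical(nCells(lt), 64L)
  expect_identical(latentMeans(embedCells(v1, tm)), latentMeans(lt))
  expect_error(trainVAE(assembleTraces(list())), "at least 2 cells")
})
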