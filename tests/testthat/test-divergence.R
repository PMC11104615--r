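test_that("KL between diagonal Gaussians matches hand and Monte-Carlo oracles", {
  expect_equal(klDiagGauss(c(1, 2), c(1, 3), c(1, 2), c(1, 3)), 0)
  expect_equal(klDiagGauss(0, 1, 1, 1), 0.5)
  expect_error(klDiagGauss(0, 1, c(0, 0), c(1, 1)), "dimension")
  expect_error(klDiagGauss(0, -1, 0, 1), "positive")
  # Monte-Carlo E_p[log p - log q] at d = 3
  set.seed(17)
  mp <- rnorm(3); vp <- exp(rnorm(3, 0, 0.4))
  mq <- rnorm(3); vq <- exp(rnorm(3, 0, 0.4))
  n <- 1e6
  z <- sweep(sweep(matrix(rnorm(n * 3), n, 3), 2, sqrt(vp), "*"), 2, mp, "+")
  ld <- function(z, m, v)
    -0.5 * rowSums(sweep(sweep(z, 2, m)^2, 2, v, "/") +
                     matrix(log(2 * pi * v), n, 3, byrow = TRUE))
  mc <- ld(z, mp, vp) - ld(z, mq, vq)
  expect_lt(abs(klDiagGauss(mp, vp, mq, vq) - mean(mc)), 3 * sd(mc) / sqrt(n))
})

test_that("symmetrized KL is symmetric with the exact 1-D value", {
  expect_equal(sklDiagGauss(0, 1, 0, 4), 0.5625)
  set.seed(18)
  for (i in 1:5) {
    mp <- rnorm(4); vp <- exp(rnorm(4)); mq <- rnorm(4); vq <- exp(rnorm(4))
    expect_equal(sklDiagGauss(mp, vp, mq, vq), sklDiagGauss(mq, vq, mp, vp))
    expect_gte(sklDiagGauss(mp, vp, mq, vq), 0)
  }
  expect_equal(sklDiagGauss(1:4, rep(2, 4), 1:4, rep(2, 4)), 0)
})

test_that("pairwise divergence matrix matches per-pair calls", {
  set.seed(19)
  lt <- LatentTable(matrix(rnorm(5 * 32), 5), matrix(exp(rnorm(5 * 32)), 5))
  D <- pairwiseSKL(lt)
  expect_identical(dim(D), c(5L, 5L))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  mu <- latentMeans(lt); va <- latentVars(lt)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], sklDiagGauss(mu[i, ], va[i, ], mu[j, ], va[j, ]),
                 tolerance = 1e-10)
  # duplicate cells -> zero divergence entry
  mu2 <- mu; mu2[2, ] <- mu2[1, ]; va2 <- va; va2[2, ] <- va2[1, ]
  D2 <- pairwiseSKL(list(mu = mu2, var = va2))
  expect_equal(D2[1, 2], 0)
})

test_that("agglomeration recovers constructed groups and is monotone", {
  # two tight groups in latent space, far apart
  set.seed(20)
  mu <- rbind(matrix(rnorm(4 * 8, 0, 0.05), 4), matrix(rnorm(4 * 8, 10, 0.05), 4))
  va <- matrix(1, 8, 8)
  D <- pairwiseSKL(list(mu = mu, var = va))
  expect_lt(max(D[1:4, 1:4]), 0.1)
  expect_gt(min(D[1:4, 5:8]), 10)
  tree <- agglomerateSKL(D)
  expect_length(tree$height, 7L)
  expect_true(all(diff(tree$height) >= -1e-12))
  # cutting just below the top merge yields the exact two-group partition
  lab <- cutClusters(tree, threshold = tree$height[7] - 1e-6)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[1:4])), 1L)
  expect_identical(length(unique(lab[5:8])), 1L)
  expect_true(lab[1] != lab[5])
  # k cuts at the extremes
  expect_identical(length(unique(cutClusters(tree, k = 8))), 8L)
  expect_identical(length(unique(cutClusters(tree, k = 1))), 1L)
  expect_error(cutClusters(tree, k = 9), "between 1")
  expect_error(cutClusters(tree), "exactly one")
  expect_error(agglomerateSKL(matrix(0, 1, 1)), "at least 2")
})

test_that("cluster summaries report counts, means and channel descriptors", {
  cfg <- generatorConfig(n_cells = 60, phenotypes = c("cluster_01", "cluster_10"),
                         weights = c(0.5, 0.5), noise_sd = 0.02, seed = 23)
  ds <- simulateDataset(cfg)
  tm <- assembleDataset(ds)
  labels <- as.integer(factor(ds@labels))
  s <- summarizeClusters(labels, tm)
  expect_equal(sum(s$counts), 60)
  expect_identical(names(s$means), as.character(sort(unique(labels))))
  # cluster of identical traces -> mean equals the common trace
  arr <- traceArray(tm)
  arr[1:5, , ] <- arr[rep(1, 5), , ]
  tm2 <- TraceMatrix(arr, time = traceTime(tm))
  s2 <- summarizeClusters(c(rep(1L, 5), rep(2L, 55)), tm2)
  expect_equal(s2$means[["1"]][1, ], arr[1, 1, ], tolerance = 1e-12)
  # generator means recovered within noise: RMS < 3 * noise sd
  m1 <- assembledMeanTrace("cluster_01")
  k1 <- s$means[[as.character(labels[ds@labels == "cluster_01"][1])]]
  expect_lt(sqrt(mean((k1 - m1)^2)), 3 * 0.02)
  expect_error(summarizeClusters(labels[1:10], tm), "align")
})
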