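test_that("latent PCA is a complete orthonormal decomposition", {
  set.seed(5)
  x <- matrix(rnorm(200 * 32), 200, 32) %*% diag(c(5:1, rep(0.2, 27)))
  pca <- fitLatentPCA(x)
  expect_equal(sum(explainedVariance(pca)), 1, tolerance = 1e-12)
  expect_true(all(diff(explainedVariance(pca)) <= 1e-12))
  # completeness: center + sum of projections reproduces every row
  sc <- projectLatent(pca, x)
  rec <- sweep(sc %*% t(pca@rotation), 2, pca@center, "+")
  expect_lt(max(abs(rec - x)), 1e-8)
  # data on a single direction -> all variance on PC1
  v <- rnorm(32); v <- v / sqrt(sum(v^2))
  x1 <- outer(rnorm(100), v)
  p1 <- fitLatentPCA(x1)
  expect_equal(explainedVariance(p1)[1], 1, tolerance = 1e-9)
  expect_error(fitLatentPCA(x[1, , drop = FALSE]), "at least 2")
})

test_that("projection matches the eigen oracle and Parseval's identity", {
  set.seed(6)
  x <- matrix(rnorm(150 * 32), 150, 32)
  pca <- fitLatentPCA(x)
  sc <- projectLatent(pca, x)
  # projecting the mean gives zero
  expect_equal(as.numeric(projectLatent(pca, matrix(colMeans(x), 1))),
               rep(0, 32), tolerance = 1e-10)
  # score variance along PC1 equals the top covariance eigenvalue
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  expect_equal(var(sc[, 1]), ev[1], tolerance = 1e-8)
  # Parseval: squared centered norm preserved
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(rowSums(sc^2), rowSums(xc^2), tolerance = 1e-8)
})

test_that("PC traversal decodes the component axis onto phenotype archetypes", {
  fx <- getSmokeVAE()
  lt <- embedCells(fx$vae, fx$tm)
  pca <- fitLatentPCA(lt)
  prof <- traversePC(fx$vae, pca, lt, component = 1L, alphas = seq(-3, 3))
  expect_identical(dim(prof), c(7L, 3L, 750L))
  # alpha = 0 decodes the latent mean, identically for every component
  mid1 <- traversePC(fx$vae, pca, lt, component = 1L, alphas = 0)
  mid2 <- traversePC(fx$vae, pca, lt, component = 2L, alphas = 0)
  expect_equal(mid1, mid2, tolerance = 1e-12)
  # endpoints align one-to-one with the two generator phenotype means
  m1 <- assembledMeanTrace("cluster_01")
  m13 <- assembledMeanTrace("cluster_13")
  ends <- prof[c(1, 7), , ]
  d <- matrix(0, 2, 2)
  for (i in 1:2) {
    d[i, 1] <- sqrt(sum((ends[i, , ] - m1)^2))
    d[i, 2] <- sqrt(sum((ends[i, , ] - m13)^2))
  }
  assign1 <- which.min(d[1, ]); assign2 <- which.min(d[2, ])
  expect_true(assign1 != assign2)
  expect_lt(d[1, assign1], d[1, assign2])
  expect_lt(d[2, assign2], d[2, assign1])
  expect_error(traversePC(fx$vae, pca, lt, component = 40L), "component")
})

test_that("spatialValues reshapes positions and values faithfully", {
  pos <- matrix(runif(20), 10, 2)
  v <- rnorm(10)
  tab <- spatialValues(pos, v)
  expect_identical(nrow(tab), 10L)
  expect_identical(tab$value, v)
  expect_identical(nrow(spatialValues(matrix(numeric(0), 0, 2), numeric(0))), 0L)
  expect_error(spatialValues(pos, v[1:5]), "align")
})
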