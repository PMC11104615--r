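test_that("sharpness scores separate sharp peaks from plateaus", {
  # identical traces -> degenerate PCA, all-zero scores, flag
  same <- matrix(rep(simulateImpactCalcium(0.5)$values, 4), 4, byrow = TRUE)
  sc0 <- sharpnessScores(same)
  expect_true(sc0$degenerate)
  expect_true(all(sc0$scores == 0))
  # sharp (0.9) vs plateau (0.1) archetypes, noise off: perfect separation
  traces <- rbind(
    t(replicate(50, simulateImpactCalcium(0.9)$values)),
    t(replicate(50, simulateImpactCalcium(0.1)$values)))
  traces <- traces + matrix(rnorm(length(traces), 0, 1e-6), nrow(traces))
  sc <- sharpnessScores(traces)
  hi <- sc$scores[1:50]; lo <- sc$scores[51:100]
  auc <- mean(outer(hi, lo, ">"))
  expect_equal(auc, 1.0)
  expect_gt(sc$evr1, 0.5)
  # zero-max traces are dropped and flagged
  tr2 <- traces; tr2[1, ] <- 0
  sc2 <- sharpnessScores(tr2)
  expect_false(sc2$kept[1])
  expect_true(is.na(sc2$scores[1]))
})

test_that("fate labelling follows the cluster-level NMP rule", {
  cfg <- generatorConfig(n_cells = 80,
                         phenotypes = c("cluster_01", "cluster_10", "cluster_13"),
                         weights = rep(1 / 3, 3), seed = 31)
  ds <- simulateDataset(cfg)
  tm <- assembleDataset(ds)
  labels <- as.integer(factor(ds@labels))
  fate <- labelFate(labels, summarizeClusters(labels, tm))
  # death phenotypes labelled dead, the viable one viable
  expect_true(all(fate[ds@labels %in% c("cluster_10", "cluster_13")] == "dead"))
  expect_true(all(fate[ds@labels == "cluster_01"] == "viable"))
  expect_false(attr(fate, "flagged"))
  expect_equal(sum(fate == "dead") + sum(fate == "viable"), 80)
  # all-viable dataset -> single label, flagged
  cfgv <- generatorConfig(n_cells = 30, phenotypes = c("cluster_01", "cluster_02"),
                          weights = c(0.5, 0.5), seed = 32)
  dsv <- simulateDataset(cfgv)
  tmv <- assembleDataset(dsv)
  lv <- as.integer(factor(dsv@labels))
  fv <- labelFate(lv, summarizeClusters(lv, tmv))
  expect_true(attr(fv, "flagged"))
})

test_that("KS wrapper: exact behaviour and the permutation oracle", {
  x <- c(0.1, 0.5, 0.9, 1.3)
  same <- ksTwoSample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  disj <- ksTwoSample(rnorm(100), rnorm(100) + 100)
  expect_equal(disj$statistic, 1)
  expect_error(ksTwoSample(numeric(0), 1:3), "non-empty")
  # n = m = 5: exact p equals exhaustive enumeration over assignments
  set.seed(4)
  a <- rnorm(5); b <- rnorm(5, 0.5)
  kt <- ksTwoSample(a, b)
  pool <- c(a, b)
  comb <- utils::combn(10, 5)
  p_enum <- mean(apply(comb, 2, function(ix)
    ksD(pool[ix], pool[-ix]) >= kt$statistic - 1e-12))
  expect_lt(abs(kt$p.value - p_enum), 1e-9)
})

test_that("late-death regression recovers a planted slope exactly", {
  # construct NMP traces whose argmax encodes death time = 2 * distance
  set.seed(41)
  n <- 30
  time <- seq(0, 3, length.out = 750)
  pos <- cbind(runif(n, 300, 400), runif(n, 300, 400))
  d <- sqrt((pos[, 1] - 330)^2 + (pos[, 2] - 330)^2)
  dt <- pmin(1.05 + (d / max(d)) * 1.8, 2.95)   # death times > 1 h
  nmp <- t(vapply(dt, function(ti) exp(-(time - ti)^2 / 0.01), numeric(750)))
  slope_true <- stats::coef(lm(time[apply(nmp, 1, which.max)] ~ d))[2]
  rep <- lateDeathRegression(nmp, pos, c(330, 330), late_cutoff = 1,
                             time = time)
  expect_equal(rep$config$slope, unname(slope_true), tolerance = 1e-9)
  expect_lt(rep$p.value, 1e-10)
  # F equals the squared t statistic of the slope
  fit <- lm(time[apply(nmp, 1, which.max)] ~ d)
  tstat <- summary(fit)$coefficients[2, "t value"]
  expect_equal(rep$statistic, tstat^2, tolerance = 1e-9)
  # insufficient data path
  few <- lateDeathRegression(nmp[1:2, ], pos[1:2, ], c(330, 330), time = time)
  expect_true(is.na(few$p.value))
  expect_true(isTRUE(attr(few, "insufficient")))
})

test_that("mito-distance KS detects spatial depolarization enrichment", {
  lib <- makePhenotypeLibrary(c("cluster_05", "cluster_10"))  # high vs no mito
  set.seed(43)
  pl <- placeCells(1000, lib, c(0.5, 0.5), impact_xy = c(330, 330))
  mito_lab <- ifelse(pl$labels == "cluster_05", "high", "low")
  rep <- mitoDistanceTest(mito_lab, pl$positions, c(330, 330))
  expect_lt(rep$p.value, 0.01)
  expect_lt(rep$config$median_low, rep$config$median_high)
  # medians are plain group medians
  dd <- sqrt(rowSums(sweep(pl$positions, 2, c(330, 330))^2))
  expect_equal(rep$config$median_high, median(dd[mito_lab == "high"]))
  expect_error(mitoDistanceTest(rep("high", 5), matrix(0, 5, 2), c(0, 0)),
               "non-empty")
})

test_that("impact-signature report aggregates per cluster correctly", {
  cfg <- generatorConfig(n_cells = 150, impact_radius_um = 250,
                         phenotypes = c("cluster_01", "cluster_10"),
                         weights = c(0.5, 0.5), seed = 44)
  ds <- simulateDataset(cfg)
  tm <- assembleDataset(ds)
  ic <- ds@impactCells
  expect_gt(length(ic), 10)
  labels <- as.integer(factor(ds@labels[ic]))
  repo <- impactSignatureReport(labels, ds@impactCalcium, tm[, ic],
                                ds@positions[ic, ])
  expect_identical(length(repo), length(unique(labels)))
  # manual grouping check
  k1 <- which(labels == 1L)
  expect_equal(repo[["1"]]$mean_impact,
               colMeans(ds@impactCalcium[k1, , drop = FALSE]))
  expect_identical(repo[["1"]]$n, length(k1))
  # dead cells were generated with high sharpness: their cluster's mean
  # impact trace peaks earlier than the viable cluster's
  dead_k <- as.character(labels[ds@labels[ic] == "cluster_10"][1])
  live_k <- as.character(labels[ds@labels[ic] == "cluster_01"][1])
  pk <- function(v) which.max(v)
  expect_lt(pk(repo[[dead_k]]$mean_impact), pk(repo[[live_k]]$mean_impact))
})
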