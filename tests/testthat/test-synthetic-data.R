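test_that("phenotype library has 14 distinct, well-formed entries", {
  lib <- makePhenotypeLibrary()
  expect_length(lib, 14L)
  # the instantaneous-death class: NMP spike at onset, no mito signal
  expect_true(!is.null(lib$cluster_10$nmp$spike))
  expect_identical(lib$cluster_10$mito$baseline, 0)
  # delayed death: calcium transient ~2 h then NMP rise
  expect_equal(lib$cluster_13$ca$transient$onset, 2.0)
  expect_gt(lib$cluster_13$nmp$rise$onset, 2.0)
  expect_length(makePhenotypeLibrary("cluster_01"), 1L)
  expect_error(makePhenotypeLibrary("cluster_99"), "unknown phenotype")
  # noiseless mean traces pairwise distinct
  time <- seq(0, 3, by = 12 / 3600)
  m <- vapply(lib, function(s) as.vector(phenotypeMeanTrace(s, time)),
              numeric(3 * length(time)))
  d <- as.matrix(dist(t(m)))
  expect_gt(min(d[upper.tri(d)]), 0)
})

test_that("simulateTrace follows the kinetics and is reproducible", {
  time <- seq(0, 3, by = 12 / 3600)
  lib <- makePhenotypeLibrary()
  # pure exponential decay -> monotone non-increasing mito channel
  tr <- simulateTrace(lib$cluster_05, time, noise_sd = 0)
  expect_true(all(diff(tr$intensities[, "mito"]) <= 0))
  # logistic rise onset = time of half-max
  spec <- lib$cluster_13
  spec$nmp <- list(baseline = 0,
                   rise = list(onset = 2.0, steepness = 8, amplitude = 1))
  tr <- simulateTrace(spec, time, noise_sd = 0)
  nmp <- tr$intensities[, "nmp"]
  t_half <- time[which.min(abs(nmp - max(nmp) / 2))]
  expect_lt(abs(t_half - 2.0), 12 / 3600 + 1e-9)
  # determinism under a fixed seed
  set.seed(7); a <- simulateTrace(lib$cluster_01, time, noise_sd = 0.1)
  set.seed(7); b <- simulateTrace(lib$cluster_01, time, noise_sd = 0.1)
  expect_identical(a, b)
  expect_error(simulateTrace(lib$cluster_01, numeric(0)), "non-empty")
  expect_error(simulateTrace(lib$cluster_01, c(1, 0.5)), "increasing")
})

test_that("impact calcium family: sample count, latency and width", {
  expect_length(simulateImpactCalcium(0.5)$values, 2400L)
  # sharpness 0 peaks late (plateau-like)
  tr0 <- simulateImpactCalcium(0)
  expect_gt(tr0$time[which.max(tr0$values)], 10)
  # FWHM strictly decreasing in sharpness
  fwhm <- function(s) {
    tr <- simulateImpactCalcium(s)
    idx <- which(tr$values >= max(tr$values) / 2)
    tr$time[max(idx)] - tr$time[min(idx)]
  }
  w <- vapply(c(0.1, 0.5, 0.9), fwhm, 0)
  expect_true(all(diff(w) < 0))
  expect_error(simulateImpactCalcium(1.5), "\\[0, 1\\]")
})

test_that("placeCells matches weights when unbiased and enriches death near impact", {
  lib <- makePhenotypeLibrary(c("cluster_01", "cluster_03", "cluster_05"))
  w <- c(0.5, 0.3, 0.2)
  set.seed(11)
  pl <- placeCells(5000, lib, w)
  freq <- table(factor(pl$labels, levels = names(lib))) / 5000
  se <- sqrt(w * (1 - w) / 5000)
  expect_true(all(abs(as.numeric(freq) - w) < 3 * se))
  # single cell inside the field
  one <- placeCells(1, lib, w)
  expect_true(all(one$positions >= 0 & one$positions <= 660))
  # death bias exp(-d/100): death cells closer to the impact
  lib2 <- makePhenotypeLibrary(c("cluster_01", "cluster_10"))
  set.seed(12)
  pl2 <- placeCells(5000, lib2, c(0.5, 0.5), impact_xy = c(330, 330))
  d <- sqrt(rowSums(sweep(pl2$positions, 2, c(330, 330))^2))
  expect_lt(median(d[pl2$labels == "cluster_10"]),
            median(d[pl2$labels == "cluster_01"]))
})

test_that("renderFrame conserves intensity over a uniform background", {
  expect_equal(renderFrame(matrix(numeric(0), 0, 2), numeric(0)),
               matrix(0, 512, 512))
  img <- renderFrame(matrix(c(330, 330), 1), 7.3, background = 0)
  expect_lt(abs(sum(img) - 7.3) / 7.3, 0.01)
  bgimg <- renderFrame(matrix(numeric(0), 0, 2), numeric(0), background = 4.2)
  expect_true(all(bgimg == 4.2))
})

test_that("dataset generation is reproducible and labels are recoverable", {
  cfg <- generatorConfig(n_cells = 40, seed = 5)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(a@traces, b@traces)
  expect_identical(a@labels, b@labels)
  expect_identical(a@impactCalcium, b@impactCalcium)
  # noiseless traces classify 100% correctly by nearest phenotype centroid
  cfg0 <- generatorConfig(n_cells = 140, noise_sd = 0, seed = 6)
  ds <- simulateDataset(cfg0)
  lib <- makePhenotypeLibrary()
  time <- ds@traces[[1]]$time
  cent <- vapply(lib, function(s) as.vector(phenotypeMeanTrace(s, time)),
                 numeric(3 * length(time)))
  pred <- vapply(ds@traces, function(tr) {
    d <- colSums((cent - as.vector(tr$intensities))^2)
    names(lib)[which.min(d)]
  }, "")
  expect_identical(pred, ds@labels)
  # impact calcium only for impact-site cells
  d <- sqrt(rowSums(sweep(ds@positions, 2, ds@impactXY)^2))
  expect_identical(which(d <= cfg0$impact_radius_um), ds@impactCells)
})
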