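# Shared fixtures, built in code at test time.

# The six-phenotype study subset used for training-scale checks: the
# dominant viable class, two high-calcium viable classes, and three
# distinct death modes (instantaneous spike, sustained NMP, delayed death
# after a calcium transient).
sixPhenotypes <- function() sprintf("cluster_%02d", c(1, 5, 6, 10, 12, 13))

# A small trained VAE shared across tests that only need *a* trained
# model (traversal, reconstruction-error pooling). Two well-separated
# phenotypes; cached for the session.
.fixture_env <- new.env(parent = emptyenv())

getSmokeVAE <- function() {
  if (!is.null(.fixture_env$smoke)) return(.fixture_env$smoke)
  cfg <- generatorConfig(n_cells = 160,
                         phenotypes = c("cluster_01", "cluster_13"),
                         weights = c(0.5, 0.5), seed = 421)
  ds <- simulateDataset(cfg)
  tm <- assembleDataset(ds)
  vae <- trainVAE(tm, config = trainConfig(epochs = 8, seed = 421))
  .fixture_env$smoke <- list(ds = ds, tm = tm, vae = vae)
  .fixture_env$smoke
}

# Noiseless phenotype mean trace pushed through the same smoothing +
# resampling as real traces (the decoder's natural comparison target).
assembledMeanTrace <- function(phenotype, duration_h = 3, frame_s = 12) {
  spec <- makePhenotypeLibrary(phenotype)[[1]]
  time <- seq(0, duration_h, by = frame_s / 3600)
  tr <- simulateTrace(spec, time, noise_sd = 0)
  tm <- assembleTraces(list(tr))
  traceArray(tm)[1, , ]
}

# Two-sample KS D statistic (independent re-implementation used as the
# enumeration oracle's statistic).
ksD <- function(a, b) {
  v <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
}
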