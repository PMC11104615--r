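# TraceVAE

Unsupervised phenotyping of single-cell, multi-channel fluorescence time
series from mechanically injured articular cartilage.

## The problem

After a superphysiologic impact, chondrocytes in cartilage explants show
coordinated responses across three stained channels — calcium
concentration, mitochondrial polarity (TMRM) and nuclear membrane
permeability (NMP, a cell-death indicator) — imaged for hours over
thousands of tracked cells per sample. Manually sorting that many traces
into behavioural phenotypes is slow and subjective. TraceVAE is for
researchers who have per-cell trace data (or want to validate the
method on synthetic data with known ground truth) and need an
unsupervised, reproducible route from raw traces to phenotype clusters
and spatial/biological hypotheses.

## The method

Each cell's 3 × 750 trace `x` is compressed by a 1-D convolutional
variational autoencoder into a diagonal-Gaussian posterior
`q_phi(z|x) = N(mu_phi(x), diag(sigma_phi(x)))` over a 32-dimensional
latent space. Training minimizes the negative evidence lower bound

    L = ||x - x_hat||^2 + D_KL( q_phi(z|x) || N(0, I) )

with the reparameterization trick (Adam, lr 0.001, batch 32, 80/20
split, N(0, 0.01) input noise). Downstream:

* **Latent PCA + decoder traversal** — what the dominant latent axes
  encode, decoded as trace profiles for alpha in -3..3.
* **Divergence clustering** — symmetrized Kullback–Leibler divergence
  between latent posteriors, closed form for diagonal Gaussians,
  followed by average-linkage agglomerative clustering with
  threshold/k cuts.
* **Timescale evaluation** — STL decomposition splits reconstruction
  error into long (trend) and short (seasonal + residual) timescales.
* **Hypothesis tests** — peracute calcium-peak *sharpness* (PC1 of the
  max-normalized impact traces) vs fate (two-sample KS); late-death
  timing vs distance to impact (regression F-test); mitochondrial
  polarity vs distance (KS).
* **Synthetic generator** — 14 kinetic phenotypes, spatially biased
  death classes, impact calcium pulses with a ground-truth sharpness
  parameter, and rendered 512 × 512 frames, so the whole pipeline can
  be validated against known truth.

The neural network (convolutions, transposed convolutions, batch norm,
Adam, backprop) is implemented in base R and verified against
finite-difference gradients and Monte-Carlo KL oracles in the test
suite.

## Worked example

```r
library(TraceVAE)

## six-phenotype synthetic study: 1 viable-dominant + 2 high-calcium
## viable + 3 death modes, 1200 cells, 3 h at 12 s/frame
cfg <- generatorConfig(n_cells = 1200,
                       phenotypes = sprintf("cluster_%02d", c(1, 5, 6, 10, 12, 13)),
                       seed = 101)
ds  <- simulateDataset(cfg)
tm  <- assembleDataset(ds)        # smooth (window 10) + resample to 750
tm
#> TraceMatrix: 1200 cells x 3 channels x 750 timepoints
#> class: TraceMatrix
#> dim: 750 1200
#> assays(3): calcium mito nmp
#> colData names(5): cell_id x y phenotype dist_impact
#> ...

vae <- trainVAE(tm, config = trainConfig(epochs = 15, seed = 1))
tail(trainingHistory(vae), 1)[, c("epoch", "train_total", "val_total")]
#>    epoch train_total val_total
#> 15    15    14.93061  11.80497

lt  <- embedCells(vae, tm)         # per-cell N(mu, diag(var)), d = 32
D   <- pairwiseSKL(lt)             # symmetrized KL, nats
lab <- cutClusters(agglomerateSKL(D), k = 6)
mclust::adjustedRandIndex(lab, ds@labels)
#> [1] 1
```

An ARI of 1 means the k = 6 cut of the sKL dendrogram recovered the six
generator phenotypes exactly. The per-epoch `val_total` is the
validation ELBO (sum-of-squares reconstruction + KL, per cell); the
trained reconstruction error is far below the variance of the data, so
the model beats the mean predictor by a wide margin.

The hypothesis layer works the same way from generated ground truth:

```r
summ <- summarizeClusters(lab, tm)
fate <- labelFate(lab, summ)              # dead / viable via NMP rule
rep  <- mitoDistanceTest(
  ifelse(ds@labels %in% sprintf("cluster_%02d", 10:14), "low", "high"),
  ds@positions, ds@impactXY)
rep
#> TestReport: mitochondrial polarity vs distance (KS)
#>   statistic = 0.4468, p = 0
#>   n = 1073, 127
```

Depolarized (low-TMRM) cells sit significantly closer to the impact
site — the generator plants that enrichment, and the test recovers it.

A full run (simulate → preprocess → train → embed → analyze → cluster →
test) with fingerprint-checked artifacts:

```r
cfg <- runConfig("out/run1", generator = generatorConfig(n_cells = 200),
                 training = trainConfig(epochs = 10), k = 6, seed = 7)
runPipeline(cfg)
```

or from a shell via `inst/scripts/pipeline.R --config run.yaml`.

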