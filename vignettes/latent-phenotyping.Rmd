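---
title: "Latent phenotyping of chondrocyte fluorescence traces with a convolutional VAE"
author: "TraceVAE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent phenotyping of chondrocyte fluorescence traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mechanical impact on articular cartilage triggers a cascade of single-cell
responses — calcium signalling within seconds, mitochondrial depolarization
and nuclear-membrane permeabilization (cell death) over hours. Confocal
imaging of stained explants yields, per experiment, thousands of cells each
described by a three-channel fluorescence time series (calcium indicator,
TMRM for mitochondrial polarity, a Sytox-type dye for nuclear membrane
permeability, hereafter NMP) plus a 2-D position and the impact-site
coordinate. Manual classification of such data is slow and subjective.

TraceVAE compresses each cell's 3 x 750 trace into a 32-dimensional
diagonal-Gaussian posterior with a convolutional variational autoencoder,
then derives phenotypes and spatial/biological conclusions from the latent
representations: principal-component traversal to visualize what the
latent axes encode, agglomerative clustering on symmetrized
Kullback-Leibler divergences between posteriors, and three hypothesis
tests connecting peracute calcium signalling, late death and
mitochondrial depolarization to fate and geometry.

## Model

### Encoder and decoder

The encoder applies three 1-D convolutions (kernel 3, stride 2, padding 1)
with channel progression (3,4), (4,8), (8,16); temporal lengths shrink
750 → 375 → 188 → 94, so the flattened feature width is 16 × 94 = 1504
(asserted at construction). A fully connected layer (1504, 256) feeds two
heads — (256, 128), (128, 32) each — producing the latent mean and
log-variance. The decoder mirrors this: (32, 128), (128, 256), (256,
1504), reshape to (B, 16, 94), then three transposed convolutions
(kernel 3, stride 2, padding 1). Their output paddings are *computed*
per stage from the target lengths 94 → 188 → 375 → 750, which gives
(1, 0, 1); no other setting restores the input length with this kernel,
stride and padding. Activations are tanh except the head outputs and
the final decoder layer, which are linear. Batch normalization follows
each encoder convolution and the first two transposed convolutions;
normalizing the final, linear output layer would destroy the output
scale, so none is applied there. Conv biases preceding batch norm are
retained for fidelity to the stated layer list even though BN makes
their gradients exactly zero.

The variance head outputs log-variance and is exponentiated, which
guarantees positivity without constraints.

### Objective and training

Training minimizes the negative evidence lower bound with a Gaussian
decoder likelihood of fixed unit variance, so the reconstruction term is
the sum of squared errors over channels and time, and the regularizer is
the closed-form KL divergence of the diagonal-Gaussian posterior to the
unit-Gaussian prior, with weight one. Latents are sampled with the
reparameterization trick. The optimizer is Adam (learning rate 0.001),
batch size 32, an 80/20 random train/validation split, and a fixed epoch
budget of at most 100 with no early stopping. Unit-Gaussian noise of
variance 0.01 is injected into the *inputs* of training samples only —
reconstruction targets stay clean, a denoising interpretation of
"robust representations". Validation losses are computed on clean
inputs in evaluation mode (batch-norm running statistics, momentum 0.1)
with the deterministic latent z = mu; clean validation makes epochs
comparable and leaves the reported losses noise-free.

The whole network — im2col convolutions, transposed convolutions as the
adjoint scatter, batch norm, and Adam — is implemented in base R matrix
code. Every layer's backward pass is verified against central finite
differences in the test suite (worst relative error ~1e-6 at probe
scale).

## Preprocessing

* **Background subtraction.** Stain leakage creates a spatially and
  temporally varying background. Each 512 x 512 frame is split into an
  8 x 8 grid; per subset, the mean of the twenty lowest non-zero pixels
  is subtracted and results clamped at zero (negatives are not
  physically meaningful for intensities). Subsets with fewer than 20
  non-zero pixels use what they have; all-zero subsets are untouched.
* **Smoothing.** Centered moving average of window 10 samples. Windows
  are truncated at the series edges (an even window cannot be exactly
  symmetric; the centre leans one sample left, the usual convention),
  so output length equals input length and constants are preserved.
* **Resampling.** Linear interpolation onto 750 uniform points spanning
  the original time range, endpoints preserved exactly. The long-term
  grid is 3 h at one frame per 12 s (901 raw samples).
  Image-level background subtraction precedes trace smoothing, matching
  the order in which the operations make sense physically.

## Synthetic data: what it emulates, and what not

The generator defines the study conditions for validation. Fourteen
kinetic phenotypes mirror the observed behaviour classes: a dominant
viable class (decaying mitochondrial polarity, low calcium, low NMP),
viable classes varying in calcium level/decay, and five death classes —
instantaneous death (NMP spike at onset), sustained high NMP with fast
calcium decay, and delayed death at roughly 1.4 or 2.2 h preceded by a
calcium transient. Kinetic primitives are the simplest forms matching
those descriptions: exponential decays, logistic rises (onset = time of
half-maximum), Gaussian-bump transients (duration = FWHM), and
spike-then-exponential-decay. Two of the fourteen behaviour-class
descriptions are qualitatively identical; the corresponding specs differ in
level/rate so that all fourteen mean traces are distinct.

Intensities are arbitrary units scaled to about [0, 1] per channel so
the linear decoder output is well-conditioned. Noise is additive i.i.d.
Gaussian per sample, clamped at zero, with default sd 0.05 — a
realistic post-smoothing signal-to-noise for confocal fluorescence
traces; absolute intensity scales and SNR vary across microscopes, so
this is a generator choice stated here once. Cells are uniform over the
660 um field; phenotype assignment probability is proportional to
phenotype weight times a spatial bias — constant for viable classes,
exp(-d/100 um) for death classes — which enriches death phenotypes near
the impact site. Peracute impact-site calcium traces (60 s at 40 fps,
2400 samples) come from a gamma-like pulse family governed by one
sharpness parameter in [0, 1]: peak latency falls from ~27 s to ~2 s
and the pulse narrows monotonically as sharpness rises; sharpness 0 is
a late broad plateau. In full datasets, death-phenotype cells draw
sharpness from Beta(5, 2) and viable cells from Beta(2, 5), tying
peracute signalling to fate.

Not emulated: optical physics, photobleaching, stain leakage dynamics
beyond the piecewise-constant background field, spontaneous calcium
spiking, cell tracking errors. Passing tests therefore demonstrate the
pipeline's correctness and statistical calibration on data with the
assumed structure, not robustness to every artefact of real microscopy.

## Analysis choices

* **Reconstruction timescales.** STL (seasonal-trend decomposition using
  LOESS) splits original and reconstructed traces additively; the
  long-timescale error is the trend difference and the short-timescale
  error the (seasonal + residual) difference, each normalized by the
  original series' standard deviation (zero-variance series fall back
  to s = 1 and are flagged). The seasonal smoother length is 35. STL
  also needs a nominal period, for which there is no canonical choice
  on aperiodic cellular traces;
  the default period of 35 samples puts transients of a few minutes
  (tens of 14.4-s resampled steps) into seasonal + residual. Both are
  configurable.
* **Latent PCA.** Centered (the standard choice; whether the original
  analysis centered is unstated — a caveat for exact reproduction), all
  32 components retained. Traversal decodes z = mean + alpha * s_i *
  e_i: the PCA mean is added back (decoding the uncentered sum would
  leave the data manifold), and alpha is in units of the
  per-component score standard deviation by default, consistent with a
  plotted range of -3..3; a raw mode is retained.
* **Divergence clustering.** Closed-form symmetrized KL between
  diagonal Gaussians, in nats. sKL is not a metric, so no metric-tree
  shortcuts are used; the pairwise matrix is O(n^2) (subsample above
  ~20,000 cells). Linkage is average by default:
  average is the common choice for non-metric
  precomputed dissimilarities and yields monotone dendrograms
  (complete and single are available). Merging and threshold/k cuts
  are delegated to `stats::hclust`/`cutree`, whose tie-breaking is
  deterministic. Decreasing a threshold only splits clusters
  (hierarchical nesting), which the suite checks explicitly.
* **Fate labelling.** A cluster is "dead" when the maximum of its mean
  NMP trace exceeds the midpoint between the dataset's lowest and
  highest cluster-level NMP maxima. The midpoint alone is relative and
  would always split even an all-viable dataset, so it is guarded by an
  absolute floor (`min_dead = 0.4` a.u. on the [0, 1] scale; generator
  death classes reach ~0.8-1.0, viable classes stay below ~0.2): if no
  cluster reaches the floor, everything is viable and the labelling is
  flagged. No canonical cutoff exists for "high/low" NMP or TMRM;
  these rules are documented stand-ins.
* **Sharpness score.** Peracute traces are normalized by their maximum
  (z-scoring available), PCA is centered, and the score is the PC1
  coordinate. A PCA sign is arbitrary; the score is oriented so that
  higher values mean *earlier* peak latency (cor(score, argmax time)
  < 0). An early-window-mass orientation was considered and rejected:
  on this pulse family the first-quartile-window mean correlates
  negatively with true sharpness (broad plateaus carry substantial
  early mass; sharp fast-decaying peaks do not), so it points the score
  backwards. KS inference is unaffected by orientation.
* **Death time.** The argmax of the NMP channel, in hours, rather than
  a threshold crossing; late death means death time > 1 h. The
  distance regression uses the overall F-test of the single-covariate
  model, which equals the squared slope t-test.
* **Multiple testing.** None is applied across the three hypotheses;
  they are illustrative procedures, not a confirmatory family.

## Problem sizes used for validation

The suite validates at sizes chosen to exercise the study conditions
while staying desk-scale: training sanity on 2000 traces of the
six-phenotype subset (clusters 1, 5, 6, 10, 12, 13 — the dominant
viable class, two high-calcium viable classes, three death modes) for
20 epochs across 3 seeds; phenotype recovery on 1200 cells with 15
epochs across 3 seeds (adjusted Rand index of the k = 6 sKL cut against
ground truth); the sharpness-fate association with 400 impact cells per
seed across 50 seeds under a logistic link (slope 6, midpoint 0.5); and
200-replicate null simulations per test for type-I calibration (the
sharpness null runs at reduced trace resolution, 4 fps, which leaves
the KS test's calibration untouched). Monte-Carlo KL oracles use 1e6
samples. `scripts/acceptance.R` re-runs the same computations from
scratch and writes the resulting numbers as JSON.

## Limitations

* The VAE reconstructs slow dynamics well but not sparse, randomly
  timed calcium transients; the short-timescale error distribution has
  the heavier tail. Spike-aware architectures are out of scope.
* Latent axes need not align with single biological processes;
  interpretation goes through decoder traversal and clustering, not
  through individual latent coordinates.
* The synthetic generator's kinetics are parametric idealizations; real
  cluster counts and p-values from the original tissue data depend on
  unavailable microscopy and are not reproduction targets.
* All computation is CPU-bound base R; at 8000+ cells the O(n^2)
  divergence matrix and the training loop dominate and benefit from
  subsampling.
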