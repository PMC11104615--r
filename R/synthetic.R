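#' Built-in phenotype library
#'
#' Fourteen kinetic phenotype specifications emulating the behavioural
#' classes observed in impacted cartilage: a dominant viable class with
#' decaying mitochondrial polarity, several viable classes differing in
#' calcium level/decay, and five death classes distinguished by how and
#' when the nuclear-membrane-permeability (NMP) signal rises (instantaneous
#' spike at imaging onset, sustained high NMP, or delayed death at roughly
#' 1.4 or 2.2 hours preceded by a calcium transient).
#'
#' Kinetic primitives per channel: exponential decay from a baseline,
#' logistic rise (onset = time of half maximum), Gaussian-bump transient,
#' and spike-then-exponential-decay. Death phenotypes carry a spatial bias
#' that decays exponentially with distance to the impact site; viable
#' phenotypes are spatially uniform. Intensities are arbitrary units scaled
#' to roughly [0, 1].
#'
#' @param subset \code{"all"} or a character vector of phenotype names
#'   (\code{"cluster_01"} ... \code{"cluster_14"}).
#' @return named list of phenotype specifications; each has fields
#'   \code{name}, \code{description}, \code{mito}, \code{ca}, \code{nmp},
#'   \code{spatial_bias} and \code{death}.
#' @examples
#' length(makePhenotypeLibrary())
#' makePhenotypeLibrary("cluster_10")[[1]]$nmp$spike
#' @export
makePhenotypeLibrary <- function(subset = "all") {
  ph <- function(name, description, mito, ca, nmp, death = FALSE) {
    list(name = name, description = description, mito = mito, ca = ca,
         nmp = nmp, death = death,
         spatial_bias = if (death) list(type = "exp_decay", scale_um = 100)
                        else list(type = "constant"))
  }
  dk <- function(baseline, decay = 0) list(baseline = baseline, decay = decay)
  lib <- list(
    ph("cluster_01", "decaying mito, low calcium, low/medium NMP",
       dk(0.50, 0.40), dk(0.15), dk(0.15)),
    ph("cluster_02", "decaying mito, medium non-decaying calcium, no NMP",
       dk(0.50, 0.40), dk(0.50), dk(0.02)),
    ph("cluster_03", "decaying mito, medium decaying calcium, no NMP",
       dk(0.50, 0.40), dk(0.50, 0.40), dk(0.02)),
    ph("cluster_04", "decaying mito, medium non-decaying calcium, no NMP (lower levels)",
       dk(0.60, 0.25), dk(0.40), dk(0.02)),
    ph("cluster_05", "high decaying mito, medium non-decaying calcium, no NMP",
       dk(0.90, 0.50), dk(0.50), dk(0.02)),
    ph("cluster_06", "high decaying mito, high decaying calcium, no NMP",
       dk(0.90, 0.50), dk(0.85, 0.50), dk(0.02)),
    ph("cluster_07", "decaying mito, high decaying calcium, no NMP",
       dk(0.50, 0.40), dk(0.85, 0.50), dk(0.02)),
    ph("cluster_08", "decaying mito, medium decaying calcium, low NMP",
       dk(0.50, 0.40), dk(0.50, 0.40), dk(0.15)),
    ph("cluster_09", "decaying mito, medium decaying calcium, no NMP (faster decay)",
       dk(0.45, 0.60), dk(0.50, 0.55), dk(0.02)),
    ph("cluster_10", "no mito, no calcium, high NMP spike at onset",
       dk(0.00), dk(0.02),
       c(dk(0.10), list(spike = list(amplitude = 0.90, decay = 1.5))),
       death = TRUE),
    ph("cluster_11", "no mito, medium decaying calcium, high NMP spike",
       dk(0.00), dk(0.50, 0.40),
       c(dk(0.15), list(spike = list(amplitude = 0.80, decay = 1.2))),
       death = TRUE),
    ph("cluster_12", "no mito, low fast-decaying calcium, high slowly-decaying NMP",
       dk(0.00), dk(0.25, 1.50), dk(0.70, 0.25), death = TRUE),
    ph("cluster_13", "no mito, calcium transient ~2 h then late NMP rise",
       dk(0.00),
       c(dk(0.10), list(transient = list(onset = 2.0, duration = 0.5, amplitude = 0.5))),
       c(dk(0.05), list(rise = list(onset = 2.2, steepness = 6, amplitude = 0.8))),
       death = TRUE),
    ph("cluster_14", "no mito, calcium fall ~1.5 h, NMP rise ~1.4 h",
       dk(0.00),
       c(dk(0.15), list(transient = list(onset = 1.0, duration = 1.0, amplitude = 0.35))),
       c(dk(0.05), list(rise = list(onset = 1.4, steepness = 6, amplitude = 0.85))),
       death = TRUE))
  names(lib) <- vapply(lib, `[[`, "", "name")
  if (identical(subset, "all")) return(lib)
  unknown <- setdiff(subset, names(lib))
  if (length(unknown))
    stop("unknown phenotype name(s): ", paste(unknown, collapse = ", "))
  lib[subset]
}

.eval_channel <- function(p, t) {
  y <- p$baseline * exp(-(p$decay %||% 0) * t)
  if (!is.null(p$transient)) {
    s <- p$transient$duration / 2.355  # FWHM -> sd
    y <- y + p$transient$amplitude * exp(-(t - p$transient$onset)^2 / (2 * s^2))
  }
  if (!is.null(p$rise))
    y <- y + p$rise$amplitude / (1 + exp(-p$rise$steepness * (t - p$rise$onset)))
  if (!is.null(p$spike))
    y <- y + p$spike$amplitude * exp(-p$spike$decay * t)
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noiseless mean trace of a phenotype
#'
#' @param spec a phenotype specification from
#'   \code{\link{makePhenotypeLibrary}}.
#' @param time numeric vector of timepoints (hours), strictly increasing.
#' @return numeric matrix, timepoints x 3, columns (calcium, mito, nmp).
#' @export
phenotypeMeanTrace <- function(spec, time) {
  stopifnot(length(time) >= 1L, all(diff(time) > 0) || length(time) == 1L)
  cbind(calcium = .eval_channel(spec$ca, time),
        mito    = .eval_channel(spec$mito, time),
        nmp     = .eval_channel(spec$nmp, time))
}

#' Simulate one cell's multi-channel trace
#'
#' Deterministic phenotype kinetics evaluated on \code{time}, plus additive
#' i.i.d. Gaussian noise of standard deviation \code{noise_sd}, clamped at
#' zero (fluorescence intensities are non-negative). Uses the global RNG;
#' seed with \code{set.seed} for reproducibility.
#'
#' @inheritParams phenotypeMeanTrace
#' @param noise_sd noise standard deviation (a.u.).
#' @return \code{list(time, intensities)} with \code{intensities} a
#'   timepoints x 3 matrix in channel order (calcium, mito, nmp).
#' @examples
#' spec <- makePhenotypeLibrary("cluster_01")[[1]]
#' tr <- simulateTrace(spec, seq(0, 3, by = 12 / 3600), noise_sd = 0)
#' @export
simulateTrace <- function(spec, time, noise_sd = 0.05) {
  if (!length(time)) stop("time grid must be non-empty")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("time grid must be strictly increasing")
  m <- phenotypeMeanTrace(spec, time)
  if (noise_sd > 0)
    m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))
  list(time = time, intensities = pmax(m, 0))
}

#' Simulate a peracute impact-site calcium trace
#'
#' Gamma-like calcium pulse over the first minute after impact. A single
#' sharpness parameter in [0, 1] controls the whole family: high sharpness
#' gives an immediate, tall, fast-decaying peak; sharpness near zero gives
#' a late, broad, plateau-like profile. Peak time moves from ~27 s
#' (sharpness 0) down to ~2 s (sharpness 1) and the pulse narrows
#' monotonically.
#'
#' @param sharpness scalar in [0, 1].
#' @param duration_s window length in seconds (default 60).
#' @param fps sampling rate, frames per second (default 40).
#' @param noise_sd additive Gaussian noise sd (default 0, clamped at 0).
#' @return \code{list(time, values)}; 2400 samples under the defaults.
#' @examples
#' tr <- simulateImpactCalcium(0.9)
#' length(tr$values)
#' @export
simulateImpactCalcium <- function(sharpness, duration_s = 60, fps = 40,
                                  noise_sd = 0) {
  if (!is.numeric(sharpness) || length(sharpness) != 1L ||
      sharpness < 0 || sharpness > 1)
    stop("sharpness must be a scalar in [0, 1]")
  n <- round(duration_s * fps)
  t <- seq_len(n) / fps
  tp <- 2 + 25 * (1 - sharpness)        # peak latency, s
  a  <- 1 + 24 * sharpness^2            # shape: larger = narrower pulse
  amp <- 0.5 + 0.5 * sharpness
  y <- amp * (t / tp)^a * exp(a * (1 - t / tp))
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  list(time = t, values = pmax(y, 0))
}

.spatial_bias <- function(bias, d) {
  switch(bias$type,
         constant  = rep(1, length(d)),
         exp_decay = exp(-d / bias$scale_um),
         stop("unknown spatial bias type: ", bias$type))
}

#' Place cells in the field and assign phenotypes
#'
#' Positions are uniform over the square field; each cell's phenotype is
#' drawn with probability proportional to \code{weights} times the
#' phenotype's spatial bias evaluated at the cell's distance to the impact
#' site (renormalized per cell). Death phenotypes with distance-decaying
#' bias are thereby enriched near the impact.
#'
#' @param n_cells number of cells.
#' @param specs phenotype library (named list).
#' @param weights numeric simplex over \code{specs} (sums to 1 within 1e-9).
#' @param field_um field side length, micrometres.
#' @param impact_xy impact-site coordinate, micrometres.
#' @return \code{list(positions, labels)}; positions cells x 2 (um).
#' @export
placeCells <- function(n_cells, specs, weights = NULL, field_um = 660,
                       impact_xy = c(330, 330)) {
  stopifnot(n_cells >= 1L, length(specs) >= 1L)
  if (is.null(weights)) weights <- rep(1 / length(specs), length(specs))
  if (length(weights) != length(specs))
    stop("weights must have one entry per phenotype")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  pos <- cbind(x = runif(n_cells, 0, field_um), y = runif(n_cells, 0, field_um))
  d <- sqrt((pos[, 1] - impact_xy[1])^2 + (pos[, 2] - impact_xy[2])^2)
  w <- vapply(specs, function(s) .spatial_bias(s$spatial_bias, d),
              numeric(n_cells))
  w <- if (n_cells == 1L) matrix(w, nrow = 1L) else w
  w <- sweep(w, 2, weights, "*")
  p <- w / rowSums(w)
  cum <- t(apply(p, 1, cumsum))
  cum <- matrix(cum, nrow = n_cells)
  cum[, ncol(cum)] <- 1
  u <- runif(n_cells)
  idx <- pmin(1L + rowSums(u >= cum), length(specs))
  list(positions = pos, labels = names(specs)[idx])
}

#' Render one microscopy-style frame
#'
#' Renders each cell as an isotropic Gaussian blob whose integrated
#' intensity equals its channel value at time \code{t}, added to a
#' piecewise-constant background defined on an 8 x 8 grid of subsets, plus
#' optional Gaussian read noise. Mimics the spatially non-uniform
#' background caused by stain leakage.
#'
#' @param positions cells x 2 matrix of positions (um); may have 0 rows.
#' @param intensities per-cell intensity at the rendered time (a.u.).
#' @param field_um field side length (um).
#' @param px image side length in pixels (default 512).
#' @param background scalar or 8 x 8 matrix of per-subset background (a.u.).
#' @param psf_sd_px blob standard deviation in pixels.
#' @param noise_sd additive Gaussian noise sd (default 0).
#' @return px x px numeric matrix, non-negative.
#' @export
renderFrame <- function(positions, intensities, field_um = 660, px = 512L,
                        background = 0, psf_sd_px = 2, noise_sd = 0) {
  positions <- matrix(positions, ncol = 2L)
  stopifnot(nrow(positions) == length(intensities))
  img <- matrix(0, px, px)
  bg <- if (length(background) == 1L) matrix(background, 8L, 8L)
        else as.matrix(background)
  stopifnot(all(dim(bg) == c(8L, 8L)), px %% 8L == 0L)
  sub <- px %/% 8L
  for (i in 1:8) for (j in 1:8)
    img[((i - 1) * sub + 1):(i * sub), ((j - 1) * sub + 1):(j * sub)] <- bg[i, j]
  scale <- px / field_um
  half <- ceiling(4 * psf_sd_px)
  for (c in seq_len(nrow(positions))) {
    cx <- positions[c, 1] * scale + 0.5
    cy <- positions[c, 2] * scale + 0.5
    ix <- max(1L, floor(cx - half)):min(px, ceiling(cx + half))
    iy <- max(1L, floor(cy - half)):min(px, ceiling(cy + half))
    if (!length(ix) || !length(iy)) next
    kx <- exp(-(ix - cx)^2 / (2 * psf_sd_px^2))
    ky <- exp(-(iy - cy)^2 / (2 * psf_sd_px^2))
    blob <- outer(kx, ky)
    img[ix, iy] <- img[ix, iy] + intensities[c] * blob / (2 * pi * psf_sd_px^2)
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(px * px, 0, noise_sd), px, px)
  pmax(img, 0)
}

#' Generator configuration
#'
#' Study conditions for the synthetic-data generator. Defaults mirror the
#' imaging protocol: a 660 um x 660 um field imaged as 512 x 512 pixels;
#' long-term traces of 3 h at one frame per 12 s; impact-site calcium at 40
#' frames per second for 60 s. Noise and impact-site geometry are generator
#' choices, stated here and discussed in the methods vignette.
#'
#' @param n_cells number of cells (>= 1).
#' @param phenotypes \code{"all"} or names into the built-in library.
#' @param weights simplex over the chosen phenotypes (default uniform).
#' @param noise_sd per-sample additive noise sd, a.u. (default 0.05).
#' @param duration_h long-term imaging duration, hours (default 3).
#' @param frame_s long-term frame interval, seconds (default 12).
#' @param impact_s impact-site window, seconds (default 60).
#' @param impact_fps impact-site frame rate (default 40).
#' @param field_um field side length, micrometres (default 660).
#' @param px frame side length, pixels (default 512).
#' @param impact_xy impact-site coordinate, um (default field centre).
#' @param impact_radius_um radius within which cells count as "at the
#'   impact site" and receive a peracute calcium trace (default 120 um).
#' @param seed integer RNG seed.
#' @return validated configuration list.
#' @export
generatorConfig <- function(n_cells = 1200L, phenotypes = "all",
                            weights = NULL, noise_sd = 0.05,
                            duration_h = 3, frame_s = 12, impact_s = 60,
                            impact_fps = 40, field_um = 660, px = 512L,
                            impact_xy = c(330, 330),
                            impact_radius_um = 120, seed = 1L) {
  stopifnot(n_cells >= 1L, duration_h > 0, frame_s > 0, impact_s > 0,
            impact_fps > 0, field_um > 0, noise_sd >= 0)
  specs <- makePhenotypeLibrary(phenotypes)
  if (is.null(weights)) weights <- rep(1 / length(specs), length(specs))
  if (abs(sum(weights) - 1) > 1e-9) stop("phenotype weights must sum to 1")
  list(n_cells = as.integer(n_cells), phenotypes = names(specs),
       weights = weights, noise_sd = noise_sd, duration_h = duration_h,
       frame_s = frame_s, impact_s = impact_s, impact_fps = impact_fps,
       field_um = field_um, px = as.integer(px), impact_xy = impact_xy,
       impact_radius_um = impact_radius_um, seed = as.integer(seed))
}

#' Simulate a full synthetic dataset
#'
#' Generates positions and phenotype labels (spatially biased; death
#' phenotypes enriched near the impact site), long-term 3-channel traces on
#' the 12-second grid, and, for cells within \code{impact_radius_um} of the
#' impact site, a peracute calcium trace. The sharpness used for each
#' impact-site cell is recorded as ground truth: death-phenotype cells draw
#' sharpness from Beta(5, 2) (sharp, early peaks) and viable cells from
#' Beta(2, 5) (broad plateaus), tying peracute signalling to fate the way
#' the downstream hypothesis tests probe it.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return a \linkS4class{SyntheticDataset}.
#' @examples
#' ds <- simulateDataset(generatorConfig(n_cells = 20, seed = 7))
#' nCells(ds)
#' @export
simulateDataset <- function(config = generatorConfig()) {
  set.seed(config$seed)
  specs <- makePhenotypeLibrary(config$phenotypes)
  pl <- placeCells(config$n_cells, specs, config$weights,
                   config$field_um, config$impact_xy)
  time <- seq(0, config$duration_h, by = config$frame_s / 3600)
  traces <- lapply(seq_len(config$n_cells), function(i)
    simulateTrace(specs[[pl$labels[i]]], time, config$noise_sd))
  d <- sqrt((pl$positions[, 1] - config$impact_xy[1])^2 +
            (pl$positions[, 2] - config$impact_xy[2])^2)
  at_impact <- which(d <= config$impact_radius_um)
  n_samp <- round(config$impact_s * config$impact_fps)
  sharp <- numeric(length(at_impact))
  ic <- matrix(0, length(at_impact), n_samp)
  for (k in seq_along(at_impact)) {
    dead <- specs[[pl$labels[at_impact[k]]]]$death
    sharp[k] <- if (dead) rbeta(1, 5, 2) else rbeta(1, 2, 5)
    ic[k, ] <- simulateImpactCalcium(sharp[k], config$impact_s,
                                     config$impact_fps,
                                     config$noise_sd)$values
  }
  methods::new("SyntheticDataset", traces = traces, labels = pl$labels,
               positions = pl$positions, impactXY = config$impact_xy,
               impactCalcium = ic, impactCells = as.integer(at_impact),
               sharpnessTruth = sharp, config = config)
}
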