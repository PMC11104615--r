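#' Grid background subtraction
#'
#' Stain leakage after impact produces a spatially and temporally
#' non-uniform background. Each frame is divided into an 8 x 8 grid of
#' square subsets; within every subset the mean of its twenty lowest
#' non-zero pixel values is subtracted and the result clamped at zero.
#' Subsets with fewer than twenty non-zero pixels use all of them;
#' all-zero subsets are left unchanged.
#'
#' @param image square numeric matrix with side divisible by 8
#'   (512 x 512 in the imaging protocol).
#' @param n_lowest number of lowest non-zero pixels averaged (default 20).
#' @return background-subtracted image, same dimensions, non-negative.
#' @examples
#' backgroundSubtract(matrix(5, 64, 64))[1, 1]  # uniform -> 0
#' @export
backgroundSubtract <- function(image, n_lowest = 20L) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be a square matrix")
  px <- nrow(image)
  if (px %% 8L != 0L) stop("image side must divide evenly into an 8x8 grid")
  sub <- px %/% 8L
  out <- image
  for (i in 1:8) for (j in 1:8) {
    ri <- ((i - 1) * sub + 1):(i * sub)
    ci <- ((j - 1) * sub + 1):(j * sub)
    block <- out[ri, ci]
    nz <- block[block > 0]
    if (!length(nz)) next
    est <- mean(sort(nz)[seq_len(min(n_lowest, length(nz)))])
    out[ri, ci] <- pmax(block - est, 0)
  }
  out
}

#' Centered moving-average smoothing
#'
#' Centered moving mean of window \code{window} (default 10, matching the
#' trace-extraction step). Output length equals input length; windows are
#' truncated (shrunken) at the series edges so no samples are lost. For an
#' even window the centre leans one sample left, the usual convention.
#'
#' @param x numeric series.
#' @param window window size in samples (>= 1, <= length(x)).
#' @return smoothed series of the same length.
#' @examples
#' movingAverage(rep(2, 30))          # constant is preserved
#' movingAverage(c(rep(0, 20), 1, rep(0, 20)))[21]  # 1/10
#' @export
movingAverage <- function(x, window = 10L) {
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window must not exceed the series length")
  if (window == 1L) return(x)
  h1 <- (window - 1L) %/% 2L
  h2 <- window - 1L - h1
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Resample a trace onto a uniform grid
#'
#' Linear interpolation onto \code{n} uniformly spaced points spanning the
#' original time range; both endpoints are preserved exactly. 750 points is
#' the fixed input dimension of the autoencoder.
#'
#' @param time numeric timestamps, strictly increasing, length >= 2.
#' @param values numeric series aligned with \code{time}.
#' @param n number of output points (default 750).
#' @return \code{list(time, values)} on the uniform grid.
#' @export
resampleTrace <- function(time, values, n = 750L) {
  if (length(time) < 2L) stop("need at least two samples to resample")
  if (any(diff(time) <= 0)) stop("timestamps must be strictly increasing")
  if (length(time) != length(values)) stop("time and values must align")
  grid <- seq(time[1L], time[length(time)], length.out = n)
  out <- approx(time, values, xout = grid)$y
  out[1L] <- values[1L]
  out[n] <- values[length(values)]
  list(time = grid, values = out)
}

#' Assemble raw traces into the fixed-size trace matrix
#'
#' Applies moving-average smoothing (window 10) then linear resampling to
#' 750 points to every channel of every cell, and stacks the results into a
#' \linkS4class{TraceMatrix} in the fixed channel order (calcium, mito,
#' nmp). Metadata (cell ids, positions, site labels) is carried through in
#' input order.
#'
#' @param traces list of cell traces, each \code{list(time, intensities)}
#'   with a timepoints x 3 intensity matrix (columns calcium, mito, nmp).
#' @param cellData optional per-cell metadata (data.frame/DataFrame).
#' @param n_out number of resampled timepoints (default 750).
#' @param window smoothing window (default 10).
#' @return a \linkS4class{TraceMatrix} of dimension cells x 3 x
#'   \code{n_out}.
#' @examples
#' ds <- simulateDataset(generatorConfig(n_cells = 5, seed = 1))
#' tm <- assembleTraces(ds@traces)
#' dim(traceArray(tm))
#' @export
assembleTraces <- function(traces, cellData = NULL, n_out = 750L,
                           window = 10L) {
  n <- length(traces)
  if (n == 0L)
    return(TraceMatrix(array(numeric(0), c(0L, 3L, n_out)),
                       time = seq_len(n_out), cellData = cellData))
  for (tr in traces)
    if (ncol(tr$intensities) != 3L)
      stop("every trace must have exactly the 3 standard channels")
  t0 <- traces[[1L]]$time
  grid <- seq(t0[1L], t0[length(t0)], length.out = n_out)
  arr <- array(0, c(n, 3L, n_out))
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    for (ch in seq_len(3L)) {
      sm <- movingAverage(tr$intensities[, ch], window)
      arr[i, ch, ] <- resampleTrace(tr$time, sm, n_out)$values
    }
  }
  TraceMatrix(arr, time = grid, cellData = cellData)
}

#' Assemble a SyntheticDataset into a TraceMatrix
#'
#' Convenience wrapper around \code{\link{assembleTraces}} that carries the
#' generator's positions and ground-truth phenotype labels into
#' \code{colData}.
#'
#' @param dataset a \linkS4class{SyntheticDataset}.
#' @inheritParams assembleTraces
#' @return a \linkS4class{TraceMatrix}.
#' @export
assembleDataset <- function(dataset, n_out = 750L, window = 10L) {
  cd <- S4Vectors::DataFrame(
    cell_id = sprintf("cell_%05d", seq_along(dataset@traces)),
    x = dataset@positions[, 1], y = dataset@positions[, 2],
    phenotype = dataset@labels,
    dist_impact = sqrt((dataset@positions[, 1] - dataset@impactXY[1])^2 +
                       (dataset@positions[, 2] - dataset@impactXY[2])^2))
  assembleTraces(dataset@traces, cellData = cd, n_out = n_out,
                 window = window)
}

#' Read per-cell traces from CSV
#'
#' Accepts external traces in the simple long-format CSV used by the
#' pipeline: columns \code{cell_id}, \code{time}, \code{calcium},
#' \code{mito}, \code{nmp}.
#'
#' @param path CSV file path.
#' @return list of cell traces suitable for \code{\link{assembleTraces}}.
#' @export
readCellTraceCSV <- function(path) {
  df <- read.csv(path)
  need <- c("cell_id", "time", "calcium", "mito", "nmp")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, factor(df$cell_id, levels = unique(df$cell_id))),
         function(d) list(time = d$time,
                          intensities = as.matrix(d[, c("calcium", "mito", "nmp")])))
}
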