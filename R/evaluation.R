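#' Seasonal-trend decomposition of a trace
#'
#' Additive STL decomposition (seasonal-trend decomposition using LOESS)
#' of a single series into trend, seasonal and residual components, used
#' to separate slow cellular drifts from short transient signals. The
#' seasonal smoother length defaults to 35, which isolates transient
#' signals lasting a few minutes on the resampled 750-point grid; STL
#' requires a nominal period, also 35 samples by default.
#'
#' @param x numeric series, length > 2 * period.
#' @param seasonal seasonal smoother span (odd; even values are rounded
#'   up). Default 35.
#' @param period nominal period in samples (default 35).
#' @return \code{list(trend, seasonal, residual)}, each the length of
#'   \code{x}; the three components sum to the input.
#' @examples
#' d <- stlDecompose(sin(2 * pi * (1:750) / 35) + (1:750) / 750)
#' max(abs(d$trend + d$seasonal + d$residual -
#'         (sin(2 * pi * (1:750) / 35) + (1:750) / 750)))
#' @export
stlDecompose <- function(x, seasonal = 35L, period = 35L) {
  seasonal <- as.integer(seasonal)
  if (seasonal %% 2L == 0L) seasonal <- seasonal + 1L
  if (length(x) <= 2L * period)
    stop("series must be longer than twice the period")
  fit <- stl(ts(x, frequency = period), s.window = seasonal)
  ts_ <- fit$time.series
  list(trend = as.numeric(ts_[, "trend"]),
       seasonal = as.numeric(ts_[, "seasonal"]),
       residual = as.numeric(ts_[, "remainder"]))
}

#' Long- and short-timescale reconstruction errors
#'
#' Decomposes the original and reconstructed trace of every channel with
#' STL and reports the normalized difference on two timescales: the long
#' timescale is the difference of trends, the short timescale the
#' difference of (seasonal + residual) components, each divided by the
#' standard deviation of the original channel series. Channels with zero
#' variance are reported as raw differences (s = 1) and flagged.
#'
#' @param x,x_hat numeric matrices, channels x timepoints, equal shape
#'   (a single series is accepted as a 1-row matrix).
#' @inheritParams stlDecompose
#' @return \code{list(long, short, scale, flagged)}: \code{long} and
#'   \code{short} are channels x timepoints matrices of normalized
#'   errors, \code{scale} the per-channel normalizer, \code{flagged} the
#'   indices of zero-variance channels.
#' @export
timescaleError <- function(x, x_hat, seasonal = 35L, period = 35L) {
  if (is.null(dim(x))) { x <- matrix(x, 1L); x_hat <- matrix(x_hat, 1L) }
  if (!identical(dim(x), dim(x_hat)))
    stop("x and x_hat must have identical shapes")
  nc <- nrow(x)
  long <- matrix(0, nc, ncol(x))
  short <- matrix(0, nc, ncol(x))
  scale <- numeric(nc)
  flagged <- integer(0)
  for (ch in seq_len(nc)) {
    s <- sd(x[ch, ])
    if (!is.finite(s) || s == 0) { s <- 1; flagged <- c(flagged, ch) }
    scale[ch] <- s
    dx <- stlDecompose(x[ch, ], seasonal, period)
    dh <- stlDecompose(x_hat[ch, ], seasonal, period)
    long[ch, ] <- (dx$trend - dh$trend) / s
    short[ch, ] <- ((dx$seasonal + dx$residual) -
                    (dh$seasonal + dh$residual)) / s
  }
  list(long = long, short = short, scale = scale, flagged = flagged)
}

#' Pooled reconstruction-error distributions for a dataset
#'
#' Applies \code{\link{timescaleError}} to every cell of a trace matrix
#' against its VAE reconstruction and pools the per-sample normalized
#' errors, the distribution summarized in reconstruction-quality figures.
#'
#' @param vae a \linkS4class{TrainedVAE}.
#' @param tm a \linkS4class{TraceMatrix}.
#' @inheritParams stlDecompose
#' @return data.frame with columns \code{cell_id}, \code{channel},
#'   \code{timescale} ("long"/"short") and \code{value}.
#' @export
reconstructionErrors <- function(vae, tm, seasonal = 35L, period = 35L) {
  x <- traceArray(tm)
  enc <- vaeEncode(vae, x)
  xhat <- vaeDecode(vae, enc$mu)
  ids <- SummarizedExperiment::colData(tm)$cell_id
  out <- vector("list", dim(x)[1])
  for (i in seq_len(dim(x)[1])) {
    te <- timescaleError(x[i, , ], xhat[i, , ], seasonal, period)
    out[[i]] <- data.frame(
      cell_id = ids[i],
      channel = rep(.CHANNELS, each = ncol(te$long), times = 2L),
      timescale = rep(c("long", "short"), each = 3L * ncol(te$long)),
      value = c(as.vector(t(te$long)), as.vector(t(te$short))))
  }
  do.call(rbind, out)
}
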