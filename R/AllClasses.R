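#' TraceMatrix: resampled multi-channel cell traces
#'
#' A \linkS4class{SummarizedExperiment} holding one assay per fluorescence
#' channel (\code{calcium}, \code{mito}, \code{nmp}), each timepoints x
#' cells. The fixed channel order is calcium concentration, mitochondrial
#' polarity (TMRM), nuclear membrane permeability. Cell metadata (positions
#' in micrometres, site labels) lives in \code{colData}; the uniform time
#' grid (hours) in \code{rowData$time}.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso \code{\link{assembleTraces}} which builds one from raw traces.
#' @export
setClass("TraceMatrix", contains = "SummarizedExperiment")

.CHANNELS <- c("calcium", "mito", "nmp")

setValidity("TraceMatrix", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!identical(an, .CHANNELS))
    return(sprintf("assays must be exactly (%s)", paste(.CHANNELS, collapse = ", ")))
  for (a in an) {
    m <- SummarizedExperiment::assay(object, a)
    if (length(m) && !all(is.finite(m)))
      return(sprintf("assay '%s' contains non-finite values", a))
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!("time" %in% colnames(rd)))
    return("rowData must carry a 'time' column (hours)")
  TRUE
})

#' Construct a TraceMatrix
#'
#' @param data numeric array, cells x 3 channels x timepoints, channel
#'   order (calcium, mito, nmp).
#' @param time numeric vector of timepoints in hours (defaults to a unit
#'   grid).
#' @param cellData optional \code{DataFrame}/data.frame of per-cell
#'   metadata (e.g. \code{cell_id}, \code{x}, \code{y}, \code{site}).
#' @return a \linkS4class{TraceMatrix}.
#' @examples
#' tm <- TraceMatrix(array(runif(2 * 3 * 50), c(2, 3, 50)))
#' nCells(tm)
#' @export
TraceMatrix <- function(data, time = NULL, cellData = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[2] == 3L)
  n <- dim(data)[1]; tp <- dim(data)[3]
  if (is.null(time)) time <- seq_len(tp)
  stopifnot(length(time) == tp)
  assays <- lapply(seq_len(3L), function(ch) {
    if (n > 0L) t(matrix(data[, ch, ], nrow = n))
    else matrix(numeric(0), nrow = tp, ncol = 0L)
  })
  names(assays) <- .CHANNELS
  if (is.null(cellData)) {
    cellData <- S4Vectors::DataFrame(cell_id = if (n) sprintf("cell_%05d", seq_len(n)) else character(0))
  } else {
    cellData <- S4Vectors::DataFrame(cellData)
    if (!("cell_id" %in% colnames(cellData)))
      cellData$cell_id <- sprintf("cell_%05d", seq_len(n))
  }
  rownames(cellData) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(time = time),
    colData = cellData)
  colnames(se) <- cellData$cell_id
  methods::new("TraceMatrix", se)
}

#' @rdname nCells
#' @export
setMethod("nCells", "TraceMatrix", function(x) ncol(x))

#' @rdname traceArray
#' @export
setMethod("traceArray", "TraceMatrix", function(x) {
  n <- ncol(x); tp <- nrow(x)
  out <- array(0, c(n, 3L, tp),
               dimnames = list(colnames(x), .CHANNELS, NULL))
  for (ch in seq_len(3L))
    out[, ch, ] <- t(SummarizedExperiment::assay(x, .CHANNELS[ch]))
  out
})

#' @rdname traceTime
#' @export
setMethod("traceTime", "TraceMatrix", function(x)
  SummarizedExperiment::rowData(x)$time)

setMethod("show", "TraceMatrix", function(object) {
  cat(sprintf("TraceMatrix: %d cells x %d channels x %d timepoints\n",
              ncol(object), 3L, nrow(object)))
  methods::callNextMethod()
})

#' LatentTable: per-cell diagonal-Gaussian latent posteriors
#'
#' The encoder maps each cell's 3-channel trace to a diagonal Gaussian
#' N(mu, diag(var)) over the 32-dimensional latent space. This container
#' holds the per-cell mean and variance vectors, aligned with cell
#' metadata.
#'
#' @slot mu numeric matrix, cells x d.
#' @slot var numeric matrix, cells x d, strictly positive.
#' @slot cellData \code{DataFrame} of per-cell metadata.
#' @export
setClass("LatentTable",
         representation(mu = "matrix", var = "matrix", cellData = "DataFrame"))

setValidity("LatentTable", function(object) {
  if (!identical(dim(object@mu), dim(object@var)))
    return("mu and var must have identical dimensions")
  if (length(object@var) && any(!is.finite(object@var) | object@var <= 0))
    return("var must be finite and strictly positive")
  if (length(object@mu) && any(!is.finite(object@mu)))
    return("mu must be finite")
  if (nrow(object@cellData) != nrow(object@mu))
    return("cellData must have one row per cell")
  TRUE
})

#' Construct a LatentTable
#'
#' @param mu,var numeric matrices, cells x d (var strictly positive).
#' @param cellData optional per-cell metadata.
#' @return a \linkS4class{LatentTable}.
#' @export
LatentTable <- function(mu, var, cellData = NULL) {
  mu <- as.matrix(mu); var <- as.matrix(var)
  if (is.null(cellData))
    cellData <- S4Vectors::DataFrame(
      cell_id = if (nrow(mu)) sprintf("cell_%05d", seq_len(nrow(mu))) else character(0))
  methods::new("LatentTable", mu = mu, var = var,
               cellData = S4Vectors::DataFrame(cellData))
}

#' @rdname latentMeans
#' @export
setMethod("latentMeans", "LatentTable", function(x) x@mu)

#' @rdname latentVars
#' @export
setMethod("latentVars", "LatentTable", function(x) x@var)

#' @rdname nCells
#' @export
setMethod("nCells", "LatentTable", function(x) nrow(x@mu))

setMethod("show", "LatentTable", function(object) {
  cat(sprintf("LatentTable: %d cells, latent dimension %d\n",
              nrow(object@mu), ncol(object@mu)))
})

#' TrainedVAE: fitted encoder/decoder parameters and training history
#'
#' @slot params list of weight/bias arrays for every layer.
#' @slot buffers list of batch-normalization running statistics.
#' @slot arch architecture description (see \code{\link{architectureSpec}}).
#' @slot config training configuration (see \code{\link{trainConfig}}).
#' @slot history data.frame of per-epoch losses.
#' @export
setClass("TrainedVAE",
         representation(params = "list", buffers = "list", arch = "list",
                        config = "list", history = "data.frame"))

setValidity("TrainedVAE", function(object) {
  h <- object@history
  if (nrow(h) && !all(is.finite(as.matrix(h[-1]))))
    return("history contains non-finite losses")
  TRUE
})

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "TrainedVAE", function(x) x@history)

setMethod("show", "TrainedVAE", function(object) {
  cat(sprintf(paste0(
    "TrainedVAE: latent dim %d, input %d x %d\n",
    "  epochs run: %d; final val total loss: %s\n"),
    object@arch$latent_dim, object@arch$channels, object@arch$input_length,
    nrow(object@history),
    if (nrow(object@history))
      format(utils::tail(object@history$val_total, 1), digits = 5) else "NA"))
})

#' LatentPCA: principal-component decomposition of latent means
#'
#' Centered PCA of the cells x 32 matrix of latent posterior means; all
#' components are retained so the basis is complete.
#'
#' @slot center numeric d-vector, the mean latent vector.
#' @slot rotation numeric d x k matrix of orthonormal components (columns).
#' @slot sdev numeric k-vector of component standard deviations.
#' @slot evr numeric k-vector, explained-variance ratio (sums to one).
#' @export
setClass("LatentPCA",
         representation(center = "numeric", rotation = "matrix",
                        sdev = "numeric", evr = "numeric"))

setValidity("LatentPCA", function(object) {
  k <- ncol(object@rotation)
  if (length(object@sdev) != k || length(object@evr) != k)
    return("sdev and evr must have one entry per component")
  if (k) {
    g <- crossprod(object@rotation)
    if (max(abs(g - diag(k))) > 1e-8)
      return("components must be orthonormal")
    if (abs(sum(object@evr) - 1) > 1e-9)
      return("explained-variance ratios must sum to 1")
    if (any(diff(object@evr) > 1e-12))
      return("explained-variance ratios must be non-increasing")
  }
  TRUE
})

#' @rdname explainedVariance
#' @export
setMethod("explainedVariance", "LatentPCA", function(x) x@evr)

setMethod("show", "LatentPCA", function(object) {
  k <- min(8L, length(object@evr))
  cat(sprintf("LatentPCA: %d components; cumulative EVR of first %d: %.1f%%\n",
              length(object@evr), k, 100 * sum(object@evr[seq_len(k)])))
})

#' SyntheticDataset: generated traces with known ground truth
#'
#' Output of \code{\link{simulateDataset}}: per-cell long-term traces,
#' phenotype labels, spatial layout, and (for cells at the impact site)
#' peracute calcium traces with the sharpness value used to generate them.
#'
#' @slot traces list of cell traces (each \code{list(time, intensities)}).
#' @slot labels character phenotype name per cell.
#' @slot positions numeric matrix, cells x 2, micrometres.
#' @slot impactXY numeric length-2 impact-site coordinate (micrometres).
#' @slot impactCalcium numeric matrix (impact-site cells x samples) or
#'   0-row matrix when no cell is at the impact site.
#' @slot impactCells integer indices of the impact-site cells.
#' @slot sharpnessTruth numeric sharpness in [0,1] per impact-site cell.
#' @slot config the generator configuration used.
#' @export
setClass("SyntheticDataset",
         representation(traces = "list", labels = "character",
                        positions = "matrix", impactXY = "numeric",
                        impactCalcium = "matrix", impactCells = "integer",
                        sharpnessTruth = "numeric", config = "list"))

setValidity("SyntheticDataset", function(object) {
  n <- length(object@traces)
  if (length(object@labels) != n) return("labels must align with traces")
  if (nrow(object@positions) != n) return("positions must align with traces")
  if (nrow(object@impactCalcium) != length(object@impactCells))
    return("impact calcium present only for the impact-site cells")
  if (length(object@sharpnessTruth) != length(object@impactCells))
    return("sharpnessTruth must align with impact-site cells")
  TRUE
})

#' @rdname nCells
#' @export
setMethod("nCells", "SyntheticDataset", function(x) length(x@traces))

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(paste0(
    "SyntheticDataset: %d cells, %d phenotypes, %d impact-site cells\n",
    "  field %.0f um, impact at (%.0f, %.0f) um\n"),
    length(object@traces), length(unique(object@labels)),
    length(object@impactCells), object@config$field_um,
    object@impactXY[1], object@impactXY[2]))
})
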