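#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom stats approx coef cor cutree hclust ks.test lm median pf
#'   prcomp rnorm runif sd setNames stl ts var quantile rbeta
#' @importFrom utils read.csv write.csv tail
NULL

#' Number of cells in an object
#'
#' @param x a \linkS4class{TraceMatrix}, \linkS4class{LatentTable} or
#'   \linkS4class{SyntheticDataset}.
#' @return integer count of cells.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Per-cell trace data as a 3-d array
#'
#' @param x a \linkS4class{TraceMatrix}.
#' @return numeric array, cells x channels x timepoints.
#' @export
setGeneric("traceArray", function(x) standardGeneric("traceArray"))

#' Time grid of a trace container (hours)
#'
#' @param x a \linkS4class{TraceMatrix}.
#' @return numeric vector of timepoints in hours.
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))

#' Latent posterior means
#'
#' @param x a \linkS4class{LatentTable}.
#' @return numeric matrix, cells x latent dimensions.
#' @export
setGeneric("latentMeans", function(x) standardGeneric("latentMeans"))

#' Latent posterior variances (diagonal covariance)
#'
#' @param x a \linkS4class{LatentTable}.
#' @return numeric matrix, cells x latent dimensions, strictly positive.
#' @export
setGeneric("latentVars", function(x) standardGeneric("latentVars"))

#' Per-epoch training history of a fitted model
#'
#' @param x a \linkS4class{TrainedVAE}.
#' @return data.frame with one row per epoch (reconstruction, KL and total
#'   loss on the training and validation split).
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Explained-variance ratio of a latent principal-component decomposition
#'
#' @param x a \linkS4class{LatentPCA}.
#' @return numeric vector summing to one, non-increasing.
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))
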