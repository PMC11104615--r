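#' Principal-component decomposition of latent means
#'
#' Centered PCA on the cells x 32 matrix of latent posterior means. All
#' components are retained, so the orthonormal basis is complete and each
#' centered latent vector is exactly the sum of its projections.
#'
#' @param x a \linkS4class{LatentTable} or a numeric matrix of latent
#'   means (cells x d), with at least 2 cells.
#' @return a \linkS4class{LatentPCA}.
#' @export
fitLatentPCA <- function(x) {
  if (methods::is(x, "LatentTable")) x <- latentMeans(x)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 cells for PCA")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  methods::new("LatentPCA", center = pc$center, rotation = pc$rotation,
               sdev = pc$sdev, evr = ev / sum(ev))
}

#' Project latent means onto principal components
#'
#' Per-cell coefficients alpha_i = (mu_z - mean_latent) . e_i.
#'
#' @param pca a \linkS4class{LatentPCA}.
#' @param x a \linkS4class{LatentTable} or matrix of latent means.
#' @return numeric matrix of scores, cells x components.
#' @export
projectLatent <- function(pca, x) {
  if (methods::is(x, "LatentTable")) x <- latentMeans(x)
  x <- as.matrix(x)
  if (ncol(x) != nrow(pca@rotation))
    stop("latent dimension does not match the decomposition")
  sweep(x, 2, pca@center) %*% pca@rotation
}

#' Decode a traversal along one principal component
#'
#' Decodes latent points z = mean_latent + alpha * s_i * e_i for each
#' requested alpha, holding all other components at zero. By default
#' alpha is in units of the per-component standard deviation of the
#' projected scores (so the conventional range -3..3 spans the data);
#' \code{scale_mode = "raw"} uses s_i = 1. The PCA mean is added back
#' before decoding so traversals stay on the data manifold.
#'
#' @param vae a \linkS4class{TrainedVAE}.
#' @param pca a \linkS4class{LatentPCA}.
#' @param latent the \linkS4class{LatentTable} the decomposition was
#'   fitted to (used for the per-component scale); ignored for
#'   \code{scale_mode = "raw"}.
#' @param component component index (1-based).
#' @param alphas numeric coefficients (default -3..3 in steps of 1).
#' @param scale_mode \code{"sd"} (default) or \code{"raw"}.
#' @return array length(alphas) x 3 x 750 of decoded profiles, in alpha
#'   order.
#' @export
traversePC <- function(vae, pca, latent = NULL, component = 1L,
                       alphas = seq(-3, 3), scale_mode = c("sd", "raw")) {
  scale_mode <- match.arg(scale_mode)
  k <- ncol(pca@rotation)
  if (component < 1L || component > k)
    stop("component must be in 1..", k)
  s_i <- if (scale_mode == "sd") {
    if (is.null(latent))
      stop("scale_mode = 'sd' needs the latent table the PCA was fit to")
    sd(projectLatent(pca, latent)[, component])
  } else 1
  z <- t(vapply(alphas, function(a)
    pca@center + a * s_i * pca@rotation[, component],
    numeric(length(pca@center))))
  vaeDecode(vae, z)
}

#' Tidy spatial table of per-cell values
#'
#' Joins positions with any per-cell quantity (for example PC scores) for
#' spatial maps.
#'
#' @param positions cells x 2 matrix (micrometres).
#' @param values numeric vector aligned with the rows of positions.
#' @return data.frame with columns \code{x}, \code{y}, \code{value}.
#' @export
spatialValues <- function(positions, values) {
  positions <- matrix(positions, ncol = 2L)
  if (nrow(positions) != length(values))
    stop("positions and values must align")
  data.frame(x = positions[, 1], y = positions[, 2], value = values)
}
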