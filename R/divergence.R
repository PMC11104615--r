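#' Kullback-Leibler divergence between diagonal Gaussians
#'
#' Closed form, in nats:
#' KL(p||q) = 0.5 * sum_i [ log(var_q_i / var_p_i) + var_p_i / var_q_i +
#' (mu_p_i - mu_q_i)^2 / var_q_i - 1 ]. Non-negative; zero iff p = q.
#'
#' @param mu_p,var_p,mu_q,var_q numeric vectors of equal length;
#'   variances strictly positive.
#' @return scalar divergence in nats.
#' @examples
#' klDiagGauss(0, 1, 1, 1)  # 0.5
#' @export
klDiagGauss <- function(mu_p, var_p, mu_q, var_q) {
  if (length(mu_p) != length(mu_q) || length(var_p) != length(var_q) ||
      length(mu_p) != length(var_p))
    stop("dimension mismatch")
  if (any(var_p <= 0) || any(var_q <= 0))
    stop("variances must be strictly positive")
  0.5 * sum(log(var_q / var_p) + var_p / var_q +
            (mu_p - mu_q)^2 / var_q - 1)
}

#' Symmetrized KL divergence between diagonal Gaussians
#'
#' D_sKL(p, q) = (KL(p||q) + KL(q||p)) / 2. Symmetric and non-negative
#' but not a metric (no triangle inequality); used as the dissimilarity
#' for hierarchical clustering of latent posteriors.
#'
#' @inheritParams klDiagGauss
#' @return scalar divergence in nats.
#' @examples
#' sklDiagGauss(0, 1, 0, 4)  # 0.5625
#' @export
sklDiagGauss <- function(mu_p, var_p, mu_q, var_q)
  0.5 * (klDiagGauss(mu_p, var_p, mu_q, var_q) +
         klDiagGauss(mu_q, var_q, mu_p, var_p))

#' Pairwise symmetrized-KL divergence matrix
#'
#' Computes D_sKL between every unordered pair of cells' latent
#' posteriors, vectorized over the closed form. O(n^2) memory: for n
#' above 20000 cells consider subsampling.
#'
#' @param latent a \linkS4class{LatentTable} (or \code{list(mu, var)}).
#' @return symmetric n x n matrix with zero diagonal, entries in nats,
#'   dimnames the cell ids when available.
#' @export
pairwiseSKL <- function(latent) {
  if (methods::is(latent, "LatentTable")) {
    mu <- latentMeans(latent); va <- latentVars(latent)
    ids <- latent@cellData$cell_id
  } else {
    mu <- as.matrix(latent$mu); va <- as.matrix(latent$var)
    ids <- rownames(mu)
  }
  n <- nrow(mu)
  if (n < 2L) stop("need at least 2 cells")
  if (any(va <= 0)) stop("variances must be strictly positive")
  d <- ncol(mu)
  iv <- 1 / va
  # sum_i var_p/var_q over pairs; and sum_i (mu_p-mu_q)^2 / var_q
  t1 <- va %*% t(iv)
  sq <- (mu * mu) %*% t(iv) -
        2 * mu %*% t(mu * iv) +
        matrix(rowSums(mu * mu * iv), n, n, byrow = TRUE)
  D <- 0.25 * (t1 + t(t1) + sq + t(sq)) - 0.5 * d
  D <- (D + t(D)) / 2
  D[D < 0] <- 0
  diag(D) <- 0
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  D
}

#' Agglomerative hierarchical clustering on a divergence matrix
#'
#' Standard bottom-up merging on the precomputed symmetrized-KL
#' divergences. Average linkage is the default: it is the common choice
#' for non-metric precomputed dissimilarities and yields monotone
#' dendrograms. No metric-tree acceleration is used (sKL does not obey
#' the triangle inequality).
#'
#' @param D symmetric divergence matrix (see \code{\link{pairwiseSKL}}).
#' @param linkage one of \code{"average"}, \code{"complete"},
#'   \code{"single"}.
#' @return an object of class \code{hclust}: \code{merge} holds the n-1
#'   merges, \code{height} the merge heights in nats.
#' @export
agglomerateSKL <- function(D, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("need at least 2 items to cluster")
  if (max(abs(D - t(D))) > 1e-8) stop("divergence matrix must be symmetric")
  hclust(stats::as.dist(D), method = linkage)
}

#' Cut a cluster tree by threshold or cluster count
#'
#' A threshold cut severs every merge whose height exceeds the threshold;
#' a k cut returns exactly k clusters. Exactly one of \code{threshold}
#' and \code{k} must be given.
#'
#' @param tree an \code{hclust} tree from \code{\link{agglomerateSKL}}.
#' @param k desired number of clusters.
#' @param threshold height cutoff in nats.
#' @return integer vector of cluster labels (contiguous from 1), with a
#'   \code{"counts"} attribute of per-cluster sizes.
#' @export
cutClusters <- function(tree, k = NULL, threshold = NULL) {
  if (is.null(k) == is.null(threshold))
    stop("give exactly one of k or threshold")
  n <- length(tree$order)
  if (!is.null(k) && (k < 1L || k > n))
    stop("k must be between 1 and the number of cells")
  labels <- if (is.null(k)) cutree(tree, h = threshold)
            else cutree(tree, k = k)
  labels <- as.integer(unname(labels))  # cutree labels are contiguous 1..k
  structure(labels, counts = tabulate(labels))
}

#' Summarize clusters over a trace matrix
#'
#' Per cluster: cell count, per-channel mean trace, and coarse channel
#' descriptors for phenotype-table reporting (mean-level tercile across
#' clusters, a monotone-decay flag on the smoothed mean trace, and the
#' peak time when an interior peak is prominent).
#'
#' @param labels integer cluster labels, one per cell.
#' @param tm the matching \linkS4class{TraceMatrix}.
#' @return list with elements \code{counts} (named integer),
#'   \code{means} (per-cluster 3 x T matrices, rows calcium/mito/nmp),
#'   and \code{table} (data.frame of descriptors, one row per cluster
#'   and channel).
#' @export
summarizeClusters <- function(labels, tm) {
  if (length(labels) != nCells(tm))
    stop("labels must align with the trace matrix")
  arr <- traceArray(tm)
  time <- traceTime(tm)
  ks <- sort(unique(labels))
  means <- lapply(ks, function(k) {
    m <- arr[labels == k, , , drop = FALSE]
    mt <- apply(m, c(2, 3), mean)
    rownames(mt) <- .CHANNELS
    mt
  })
  names(means) <- as.character(ks)
  lvl <- vapply(means, function(m) rowMeans(m), numeric(3L))  # 3 x K
  rows <- list()
  for (ci in seq_len(3L)) {
    terc <- cut(lvl[ci, ], breaks = quantile(lvl[ci, ], c(0, 1/3, 2/3, 1)),
                labels = c("low", "medium", "high"), include.lowest = TRUE)
    for (ki in seq_along(ks)) {
      m <- means[[ki]][ci, ]
      sm <- movingAverage(m, min(25L, length(m)))
      decaying <- all(diff(sm) <= sd(m) * 0.05 + 1e-9) && sm[1] > tail(sm, 1)
      pk <- which.max(m)
      peak_time <- if (pk > 1 && pk < length(m) &&
                       m[pk] > min(m) + 3 * sd(diff(m))) time[pk] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = ks[ki], channel = .CHANNELS[ci],
        mean_level = lvl[ci, ki], level_tercile = as.character(terc[ki]),
        monotone_decay = decaying, peak_time = peak_time)
    }
  }
  list(counts = setNames(tabulate(factor(labels, levels = ks)),
                         as.character(ks)),
       means = means, table = do.call(rbind, rows))
}
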