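#' Calcium-peak sharpness scores from peracute traces
#'
#' Each impact-site calcium trace is normalized by its maximum, and
#' centered PCA is run across cells; the first principal-component
#' coordinate parameterizes the family of peak shapes from immediate
#' sharp peaks with fast decay to late broad plateaus. The sign of the
#' component is arbitrary in PCA, so it is oriented so that higher scores
#' correlate negatively with peak latency (the time of the trace maximum):
#' sharper, earlier peaks score higher. Zero-maximum traces are dropped and
#' flagged; an all-identical input yields all-zero scores and a flag.
#'
#' @param traces numeric matrix, cells x timepoints (>= 2 cells).
#' @param normalize \code{"max"} (default, per-trace division by the
#'   maximum) or \code{"zscore"}.
#' @return list with \code{scores} (named by row when rownames exist,
#'   NA for dropped cells), \code{evr1} (PC1 explained-variance ratio),
#'   \code{kept} (logical), \code{degenerate} flag.
#' @export
sharpnessScores <- function(traces, normalize = c("max", "zscore")) {
  normalize <- match.arg(normalize)
  traces <- as.matrix(traces)
  if (nrow(traces) < 2L) stop("need at least 2 cells")
  mx <- apply(traces, 1, max)
  kept <- is.finite(mx) & mx > 0
  norm <- traces[kept, , drop = FALSE]
  norm <- switch(normalize,
    max = norm / apply(norm, 1, max),
    zscore = {
      s <- apply(norm, 1, sd); s[s == 0] <- 1
      (norm - rowMeans(norm)) / s
    })
  scores_all <- rep(NA_real_, nrow(traces))
  tot_var <- sum(apply(norm, 2, var))
  if (!is.finite(tot_var) || tot_var == 0) {
    scores_all[kept] <- 0
    return(list(scores = scores_all, evr1 = NA_real_, kept = kept,
                degenerate = TRUE))
  }
  pc <- prcomp(norm, center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1]
  peak_latency <- apply(norm, 1, which.max)
  orient <- suppressWarnings(cor(sc, peak_latency))
  if (is.finite(orient) && orient > 0) sc <- -sc
  scores_all[kept] <- sc
  list(scores = scores_all, evr1 = pc$sdev[1]^2 / sum(pc$sdev^2),
       kept = kept, degenerate = FALSE)
}

#' Label clusters (and their cells) as dead or viable
#'
#' A cluster is labelled dead when the maximum of its mean
#' nuclear-membrane-permeability trace exceeds the rule threshold; cells
#' inherit their cluster's label. The default rule is the midpoint
#' between the lowest and highest cluster-level NMP maxima in the
#' dataset, a documented stand-in for the visual high/low NMP call. The
#' midpoint is a relative rule, so it is additionally guarded by an
#' absolute floor: when no cluster's NMP maximum reaches
#' \code{min_dead} (death-indicating signal on the [0, 1] intensity
#' scale), every cell is labelled viable and the result is flagged.
#'
#' @param labels integer cluster labels per cell.
#' @param summary output of \code{\link{summarizeClusters}} for those
#'   labels.
#' @param nmp_rule numeric threshold; \code{NULL} (default) uses the
#'   midpoint rule.
#' @param min_dead absolute NMP floor for any death call (default 0.4).
#' @return factor of \code{"dead"}/\code{"viable"} per cell with
#'   attributes \code{threshold}, \code{cluster_max} and \code{flagged}
#'   (TRUE when only one cluster or one fate label is present).
#' @export
labelFate <- function(labels, summary, nmp_rule = NULL, min_dead = 0.4) {
  cmax <- vapply(summary$means, function(m) max(m["nmp", ]), 0)
  thr <- if (is.null(nmp_rule)) (min(cmax) + max(cmax)) / 2 else nmp_rule
  dead_clusters <- if (is.null(nmp_rule) && max(cmax) < min_dead)
    character(0) else names(cmax)[cmax > thr]
  fate <- factor(ifelse(as.character(labels) %in% dead_clusters,
                        "dead", "viable"),
                 levels = c("dead", "viable"))
  flagged <- length(cmax) < 2L || length(unique(fate)) < 2L
  structure(fate, threshold = thr, cluster_max = cmax, flagged = flagged)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test of two empirical distributions; exact p-value via
#' distribution enumeration when n * m <= 10^4 (and no ties), asymptotic
#' otherwise.
#'
#' @param a,b numeric samples, both non-empty.
#' @return \code{list(statistic, p.value, n, m, exact)}.
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  exact <- length(a) * length(b) <= 1e4
  kt <- suppressWarnings(ks.test(a, b, exact = exact))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       n = length(a), m = length(b), exact = exact)
}

.test_report <- function(test, statistic, p.value, sizes, config = list()) {
  structure(list(test = test, statistic = statistic, p.value = p.value,
                 sizes = sizes, config = config),
            class = "TestReport")
}

#' @export
print.TestReport <- function(x, ...) {
  cat(sprintf("TestReport: %s\n  statistic = %.4g, p = %.4g\n  n = %s\n",
              x$test, x$statistic, x$p.value,
              paste(unlist(x$sizes), collapse = ", ")))
  invisible(x)
}

#' Regression test of late-death timing on distance to impact
#'
#' Death time is the time (hours) at which a cell's NMP channel reaches
#' its maximum. Cells dying later than \code{late_cutoff} are regressed
#' (simple linear regression) on their Euclidean distance to the impact
#' site; the overall regression F-test (1 numerator df, equivalent to the
#' slope test) provides the p-value. Under the biological null the
#' timing of late death is unrelated to distance.
#'
#' @param tm a \linkS4class{TraceMatrix} (NMP channel + time grid), or a
#'   numeric matrix of NMP traces with a \code{time} attribute supplied
#'   via \code{time}.
#' @param positions cells x 2 matrix (micrometres).
#' @param impact_xy impact-site coordinate (micrometres).
#' @param late_cutoff hours; only deaths after this count (default 1).
#' @param time optional time grid when \code{tm} is a plain matrix.
#' @return a \code{TestReport} with slope, F statistic, p-value and the
#'   number of qualifying cells; when fewer than 3 cells qualify the
#'   report carries \code{p.value = NA} and an \code{insufficient} flag.
#' @export
lateDeathRegression <- function(tm, positions, impact_xy, late_cutoff = 1,
                                time = NULL) {
  if (methods::is(tm, "TraceMatrix")) {
    nmp <- t(SummarizedExperiment::assay(tm, "nmp"))
    time <- traceTime(tm)
  } else nmp <- as.matrix(tm)
  if (is.null(time)) stop("a time grid (hours) is required")
  positions <- matrix(positions, ncol = 2L)
  death_time <- time[apply(nmp, 1, which.max)]
  d <- sqrt((positions[, 1] - impact_xy[1])^2 +
            (positions[, 2] - impact_xy[2])^2)
  late <- death_time > late_cutoff
  if (sum(late) < 3L)
    return(structure(.test_report("late-death timing ~ distance (F-test)",
                                  NA_real_, NA_real_,
                                  list(n_late = sum(late)),
                                  list(late_cutoff = late_cutoff)),
                     insufficient = TRUE))
  fit <- lm(death_time[late] ~ d[late])
  fs <- summary(fit)$fstatistic
  p <- pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  rep <- .test_report("late-death timing ~ distance (F-test)",
                      unname(fs[1]), unname(p),
                      list(n_late = sum(late)),
                      list(late_cutoff = late_cutoff,
                           slope = unname(coef(fit)[2]),
                           df = unname(fs[2:3])))
  rep
}

#' KS test of mitochondrial polarity groups against distance to impact
#'
#' Compares the distance-to-impact distributions of high- and
#' low-polarity (TMRM) cells with a two-sample KS test; mitochondrial
#' depolarization concentrated near the impact shows up as a smaller
#' low-group median.
#'
#' @param labels factor/character of \code{"high"}/\code{"low"} per cell.
#' @param positions cells x 2 matrix (micrometres).
#' @param impact_xy impact-site coordinate.
#' @return a \code{TestReport}; \code{config} carries both group medians.
#' @export
mitoDistanceTest <- function(labels, positions, impact_xy) {
  positions <- matrix(positions, ncol = 2L)
  d <- sqrt((positions[, 1] - impact_xy[1])^2 +
            (positions[, 2] - impact_xy[2])^2)
  hi <- d[labels == "high"]; lo <- d[labels == "low"]
  if (!length(hi) || !length(lo))
    stop("both 'high' and 'low' groups must be non-empty")
  kt <- ksTwoSample(hi, lo)
  .test_report("mitochondrial polarity vs distance (KS)",
               kt$statistic, kt$p.value,
               list(n_high = length(hi), n_low = length(lo)),
               list(median_high = median(hi), median_low = median(lo)))
}

#' Sharpness vs fate KS test
#'
#' Scores peracute calcium traces with \code{\link{sharpnessScores}} and
#' compares the dead and viable score distributions with a two-sample KS
#' test — the association between calcium-peak sharpness and cell death.
#'
#' @param impact_calcium cells x timepoints matrix of peracute traces.
#' @param fate factor of \code{"dead"}/\code{"viable"} aligned with rows.
#' @return a \code{TestReport}; \code{config} carries the PC1 EVR.
#' @export
sharpnessFateTest <- function(impact_calcium, fate) {
  sc <- sharpnessScores(impact_calcium)
  ok <- sc$kept & !is.na(sc$scores)
  a <- sc$scores[ok & fate == "dead"]
  b <- sc$scores[ok & fate == "viable"]
  if (!length(a) || !length(b))
    stop("both fate groups must be non-empty")
  kt <- ksTwoSample(a, b)
  .test_report("calcium sharpness vs fate (KS)", kt$statistic, kt$p.value,
               list(n_dead = length(a), n_viable = length(b)),
               list(evr1 = sc$evr1))
}

#' Per-cluster impact-signature report
#'
#' Joined view linking long-term clusters at the impact site to their
#' peracute calcium signatures: per cluster, the mean impact calcium
#' trace, the mean long-term 3-channel trace, member positions and count.
#'
#' @param labels cluster labels for the impact-site cells.
#' @param impact_calcium impact-site cells x timepoints matrix.
#' @param tm \linkS4class{TraceMatrix} restricted to the impact-site
#'   cells.
#' @param positions impact-site cells x 2 matrix.
#' @return named list, one entry per cluster, each with \code{n},
#'   \code{mean_impact}, \code{mean_longterm}, \code{positions}.
#' @export
impactSignatureReport <- function(labels, impact_calcium, tm, positions) {
  if (!length(labels)) stop("no impact-site cells")
  stopifnot(length(labels) == nrow(impact_calcium),
            length(labels) == nCells(tm))
  positions <- matrix(positions, ncol = 2L)
  arr <- traceArray(tm)
  ks <- sort(unique(labels))
  out <- lapply(ks, function(k) {
    idx <- which(labels == k)
    list(n = length(idx),
         mean_impact = colMeans(impact_calcium[idx, , drop = FALSE]),
         mean_longterm = apply(arr[idx, , , drop = FALSE], c(2, 3), mean),
         positions = positions[idx, , drop = FALSE])
  })
  names(out) <- as.character(ks)
  out
}
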