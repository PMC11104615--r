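# Reproducible orchestration: each stage reads the previous stage's
# artifacts, checks their fingerprints, and writes its own files plus a
# JSON sidecar recording the configuration, derived seed and input
# fingerprints. Artifacts are plain text (CSV/JSON) except model
# checkpoints, which are RDS with a JSON sidecar.

.STAGES <- c("simulate", "preprocess", "train", "embed", "analyze",
             "cluster", "test")

#' Derive a per-stage seed from the global seed
#'
#' One global seed fans out deterministically to stage seeds so stages
#' can be rerun independently yet reproducibly.
#'
#' @param seed global integer seed.
#' @param stage stage name (one of simulate, preprocess, train, embed,
#'   analyze, cluster, test).
#' @return integer seed below 2^31.
#' @export
stageSeed <- function(seed, stage) {
  i <- match(stage, .STAGES)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + i * 10007) %% .Machine$integer.max)
}

.fingerprint <- function(path) unname(tools::md5sum(path))

.write_sidecar <- function(path, stage, seed, inputs = character(0),
                           config = list()) {
  meta <- list(stage = stage, seed = seed,
               inputs = as.list(inputs),
               config = config,
               package_version = as.character(utils::packageVersion("TraceVAE")))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

.check_fingerprint <- function(file, recorded) {
  actual <- .fingerprint(file)
  if (!identical(unname(actual), unname(recorded)))
    stop("fingerprint mismatch for ", file,
         ": artifact does not match the recorded upstream run ",
         "(expected ", recorded, ", found ", actual, ")")
  invisible(TRUE)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory for all artifacts.
#' @param generator a \code{\link{generatorConfig}}.
#' @param training a \code{\link{trainConfig}}.
#' @param k number of clusters for the cut (default 6); set
#'   \code{threshold} instead for a height cut.
#' @param threshold optional dendrogram height cut (nats).
#' @param linkage clustering linkage (default "average").
#' @param stl_period STL period in samples (default 35).
#' @param late_cutoff late-death cutoff in hours (default 1).
#' @param seed global seed, fanned out per stage via
#'   \code{\link{stageSeed}}.
#' @return configuration list.
#' @export
runConfig <- function(out_dir, generator = generatorConfig(),
                      training = trainConfig(), k = 6L, threshold = NULL,
                      linkage = "average", stl_period = 35L,
                      late_cutoff = 1, seed = 1L) {
  list(out_dir = out_dir, generator = generator, training = training,
       k = k, threshold = threshold, linkage = linkage,
       stl_period = stl_period, late_cutoff = late_cutoff,
       seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{runConfig}};
#' \code{generator} and \code{training} are nested maps passed to
#' \code{\link{generatorConfig}} and \code{\link{trainConfig}}.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- do.call(generatorConfig, y$generator %||% list())
  trn <- do.call(trainConfig, y$training %||% list())
  runConfig(out_dir = y$out_dir %||% ".",
            generator = gen, training = trn,
            k = y$k %||% 6L, threshold = y$threshold,
            linkage = y$linkage %||% "average",
            stl_period = y$stl_period %||% 35L,
            late_cutoff = y$late_cutoff %||% 1,
            seed = y$seed %||% 1L)
}

#' Write / read a synthetic dataset as a plain-text dataset directory
#'
#' Layout: \code{traces.csv} (long format: cell_id, time, calcium, mito,
#' nmp), \code{cells.csv} (positions, labels), \code{impact_calcium.csv},
#' and \code{manifest.json} with the generator config and file
#' fingerprints.
#'
#' @param dataset a \linkS4class{SyntheticDataset}.
#' @param dir target directory (created if needed).
#' @return (invisibly) the directory.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nCells(dataset)
  tlen <- length(dataset@traces[[1]]$time)
  long <- data.frame(
    cell_id = rep(sprintf("cell_%05d", seq_len(n)), each = tlen),
    time = rep(dataset@traces[[1]]$time, n),
    calcium = unlist(lapply(dataset@traces, function(t) t$intensities[, 1])),
    mito = unlist(lapply(dataset@traces, function(t) t$intensities[, 2])),
    nmp = unlist(lapply(dataset@traces, function(t) t$intensities[, 3])))
  write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  cells <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n)),
                      x = dataset@positions[, 1], y = dataset@positions[, 2],
                      phenotype = dataset@labels,
                      at_impact = seq_len(n) %in% dataset@impactCells)
  write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  ic <- dataset@impactCalcium
  icd <- data.frame(cell_id = sprintf("cell_%05d", dataset@impactCells),
                    sharpness = dataset@sharpnessTruth)
  if (nrow(ic)) icd <- cbind(icd, as.data.frame(ic))
  write.csv(icd, file.path(dir, "impact_calcium.csv"), row.names = FALSE)
  files <- c("traces.csv", "cells.csv", "impact_calcium.csv")
  manifest <- list(
    config = dataset@config, impact_xy = dataset@impactXY,
    fingerprints = as.list(setNames(
      vapply(file.path(dir, files), .fingerprint, ""), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeDataset
#' @export
readDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest$fingerprints))
    .check_fingerprint(file.path(dir, f), manifest$fingerprints[[f]])
  traces <- readCellTraceCSV(file.path(dir, "traces.csv"))
  cells <- read.csv(file.path(dir, "cells.csv"))
  icd <- read.csv(file.path(dir, "impact_calcium.csv"))
  impact_cells <- match(icd$cell_id, cells$cell_id)
  ic <- as.matrix(icd[, setdiff(names(icd), c("cell_id", "sharpness")),
                      drop = FALSE])
  dimnames(ic) <- NULL
  cfg <- manifest$config
  methods::new("SyntheticDataset",
               traces = unname(traces), labels = cells$phenotype,
               positions = cbind(cells$x, cells$y),
               impactXY = as.numeric(manifest$impact_xy),
               impactCalcium = ic, impactCells = as.integer(impact_cells),
               sharpnessTruth = as.numeric(icd$sharpness),
               config = cfg)
}

#' Pipeline stages
#'
#' Thin, idempotent commands chaining simulation to test reports. Each
#' writes its artifacts plus a JSON sidecar with the derived seed and the
#' fingerprints of its inputs; downstream stages refuse inputs whose
#' fingerprints do not match (prevents mixing runs).
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return each stage invisibly returns the paths it wrote.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmdSimulate <- function(cfg) {
  gen <- cfg$generator
  gen$seed <- stageSeed(cfg$seed, "simulate")
  ds <- simulateDataset(gen)
  dir <- file.path(cfg$out_dir, "dataset")
  writeDataset(ds, dir)
  invisible(dir)
}

#' @rdname pipeline
#' @export
cmdPreprocess <- function(cfg) {
  dir <- file.path(cfg$out_dir, "dataset")
  ds <- readDataset(dir)
  tm <- assembleDataset(ds)
  path <- file.path(cfg$out_dir, "trace_matrix.csv")
  writeTraceMatrix(tm, path)
  .write_sidecar(file.path(cfg$out_dir, "trace_matrix.json"), "preprocess",
                 stageSeed(cfg$seed, "preprocess"),
                 inputs = c(dataset = .fingerprint(file.path(dir, "traces.csv"))),
                 config = list(n_out = 750L, window = 10L))
  invisible(path)
}

#' @rdname pipeline
#' @export
cmdTrain <- function(cfg) {
  path <- file.path(cfg$out_dir, "trace_matrix.csv")
  tm <- readTraceMatrix(path)
  trn <- cfg$training
  trn$seed <- stageSeed(cfg$seed, "train")
  vae <- trainVAE(tm, config = trn)
  ckpt <- file.path(cfg$out_dir, "vae_checkpoint.rds")
  saveRDS(vae, ckpt)
  write.csv(trainingHistory(vae), file.path(cfg$out_dir, "history.csv"),
            row.names = FALSE)
  .write_sidecar(file.path(cfg$out_dir, "vae_checkpoint.json"), "train",
                 trn$seed,
                 inputs = c(trace_matrix = .fingerprint(path)),
                 config = trn)
  invisible(ckpt)
}

.load_checkpoint <- function(cfg) {
  ckpt <- file.path(cfg$out_dir, "vae_checkpoint.rds")
  side <- jsonlite::read_json(file.path(cfg$out_dir, "vae_checkpoint.json"),
                              simplifyVector = TRUE)
  .check_fingerprint(file.path(cfg$out_dir, "trace_matrix.csv"),
                     side$inputs$trace_matrix)
  readRDS(ckpt)
}

#' @rdname pipeline
#' @export
cmdEmbed <- function(cfg) {
  vae <- .load_checkpoint(cfg)
  tm <- readTraceMatrix(file.path(cfg$out_dir, "trace_matrix.csv"))
  lt <- embedCells(vae, tm)
  path <- file.path(cfg$out_dir, "latents.csv")
  writeLatentTable(lt, path)
  .write_sidecar(file.path(cfg$out_dir, "latents.json"), "embed",
                 stageSeed(cfg$seed, "embed"),
                 inputs = c(trace_matrix =
                   .fingerprint(file.path(cfg$out_dir, "trace_matrix.csv"))))
  invisible(path)
}

#' @rdname pipeline
#' @export
cmdAnalyze <- function(cfg) {
  vae <- .load_checkpoint(cfg)
  lt <- readLatentTable(file.path(cfg$out_dir, "latents.csv"))
  pca <- fitLatentPCA(lt)
  write.csv(data.frame(component = seq_along(pca@evr), evr = pca@evr),
            file.path(cfg$out_dir, "evr.csv"), row.names = FALSE)
  alph <- projectLatent(pca, lt)
  colnames(alph) <- sprintf("alpha_%02d", seq_len(ncol(alph)) - 1L)
  write.csv(cbind(data.frame(cell_id = lt@cellData$cell_id), alph),
            file.path(cfg$out_dir, "alphas.csv"), row.names = FALSE)
  prof <- traversePC(vae, pca, lt, component = 1L)
  long <- do.call(rbind, lapply(seq_len(dim(prof)[1]), function(i)
    data.frame(alpha = seq(-3, 3)[i],
               channel = rep(.CHANNELS, each = dim(prof)[3]),
               t = rep(seq_len(dim(prof)[3]), 3L),
               value = as.vector(t(prof[i, , ])))))
  write.csv(long, file.path(cfg$out_dir, "traversal_pc1.csv"),
            row.names = FALSE)
  invisible(file.path(cfg$out_dir, c("evr.csv", "alphas.csv",
                                     "traversal_pc1.csv")))
}

#' @rdname pipeline
#' @export
cmdCluster <- function(cfg) {
  lt <- readLatentTable(file.path(cfg$out_dir, "latents.csv"))
  D <- pairwiseSKL(lt)
  tree <- agglomerateSKL(D, cfg$linkage)
  labels <- if (!is.null(cfg$threshold))
    cutClusters(tree, threshold = cfg$threshold)
  else cutClusters(tree, k = cfg$k)
  write.csv(data.frame(cell_id = lt@cellData$cell_id,
                       cluster = as.integer(labels)),
            file.path(cfg$out_dir, "clusters.csv"), row.names = FALSE)
  write.csv(data.frame(left = tree$merge[, 1], right = tree$merge[, 2],
                       height = tree$height),
            file.path(cfg$out_dir, "tree.csv"), row.names = FALSE)
  .write_sidecar(file.path(cfg$out_dir, "clusters.json"), "cluster",
                 stageSeed(cfg$seed, "cluster"),
                 inputs = c(latents =
                   .fingerprint(file.path(cfg$out_dir, "latents.csv"))),
                 config = list(linkage = cfg$linkage, k = cfg$k,
                               threshold = cfg$threshold))
  invisible(file.path(cfg$out_dir, "clusters.csv"))
}

#' @rdname pipeline
#' @export
cmdTest <- function(cfg) {
  tm <- readTraceMatrix(file.path(cfg$out_dir, "trace_matrix.csv"))
  cl <- read.csv(file.path(cfg$out_dir, "clusters.csv"))
  ds <- readDataset(file.path(cfg$out_dir, "dataset"))
  labels <- cl$cluster
  summ <- summarizeClusters(labels, tm)
  fate <- labelFate(labels, summ)
  pos <- ds@positions
  reports <- list()
  if (length(ds@impactCells) >= 4L &&
      nlevels(droplevels(fate[ds@impactCells])) == 2L)
    reports$sharpness <- sharpnessFateTest(ds@impactCalcium,
                                           droplevels(fate[ds@impactCells]))
  reports$late_death <- lateDeathRegression(tm, pos, ds@impactXY,
                                            cfg$late_cutoff)
  mito_level <- vapply(summ$means, function(m) mean(m["mito", ]), 0)
  mito_lab <- ifelse(mito_level[as.character(labels)] >
                       (min(mito_level) + max(mito_level)) / 2,
                     "high", "low")
  if (length(unique(mito_lab)) == 2L)
    reports$mito <- mitoDistanceTest(mito_lab, pos, ds@impactXY)
  path <- file.path(cfg$out_dir, "reports.json")
  jsonlite::write_json(lapply(reports, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulation, preprocessing, VAE training, embedding, latent analysis,
#' clustering and hypothesis tests, in order, into
#' \code{cfg$out_dir}.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @return (invisibly) \code{cfg$out_dir}.
#' @export
runPipeline <- function(cfg) {
  cmdSimulate(cfg)
  cmdPreprocess(cfg)
  cmdTrain(cfg)
  cmdEmbed(cfg)
  cmdAnalyze(cfg)
  cmdCluster(cfg)
  cmdTest(cfg)
  invisible(cfg$out_dir)
}

#' Write / read a TraceMatrix as CSV
#'
#' Wide CSV: one row per cell, metadata columns first, then
#' \code{<channel>_<t>} columns for the three channels. The time grid
#' (hours) is written to a companion \code{*_time.csv} file alongside.
#'
#' @param tm a \linkS4class{TraceMatrix}.
#' @param path CSV path.
#' @return (invisibly) the path.
#' @export
writeTraceMatrix <- function(tm, path) {
  arr <- traceArray(tm)
  n <- dim(arr)[1]; tp <- dim(arr)[3]
  cd <- as.data.frame(SummarizedExperiment::colData(tm))
  flat <- do.call(cbind, lapply(seq_len(3L), function(ch) {
    m <- matrix(arr[, ch, ], n, tp)
    colnames(m) <- sprintf("%s_%04d", .CHANNELS[ch], seq_len(tp))
    m
  }))
  out <- cbind(cd, as.data.frame(flat))
  tfile <- sub("\\.csv$", "_time.csv", path)
  write.csv(data.frame(time = traceTime(tm)), tfile, row.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceMatrix
#' @export
readTraceMatrix <- function(path) {
  df <- read.csv(path)
  tfile <- sub("\\.csv$", "_time.csv", path)
  time <- read.csv(tfile)$time
  tp <- length(time)
  meta_cols <- setdiff(names(df), sprintf("%s_%04d",
    rep(.CHANNELS, each = tp), rep(seq_len(tp), 3L)))
  n <- nrow(df)
  arr <- array(0, c(n, 3L, tp))
  for (ch in seq_len(3L))
    arr[, ch, ] <- as.matrix(df[, sprintf("%s_%04d", .CHANNELS[ch],
                                          seq_len(tp))])
  TraceMatrix(arr, time = time, cellData = df[, meta_cols, drop = FALSE])
}

#' Write / read a LatentTable as CSV
#'
#' Columns: \code{cell_id}, \code{mu_0..mu_{d-1}}, \code{var_0..var_{d-1}}.
#'
#' @param lt a \linkS4class{LatentTable}.
#' @param path CSV path.
#' @return (invisibly) the path.
#' @export
writeLatentTable <- function(lt, path) {
  d <- ncol(lt@mu)
  mu <- lt@mu; colnames(mu) <- sprintf("mu_%d", seq_len(d) - 1L)
  va <- lt@var; colnames(va) <- sprintf("var_%d", seq_len(d) - 1L)
  write.csv(cbind(data.frame(cell_id = lt@cellData$cell_id), mu, va),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLatentTable
#' @export
readLatentTable <- function(path) {
  df <- read.csv(path)
  mu <- as.matrix(df[, grep("^mu_", names(df)), drop = FALSE])
  va <- as.matrix(df[, grep("^var_", names(df)), drop = FALSE])
  dimnames(mu) <- NULL; dimnames(va) <- NULL
  LatentTable(mu, va, cellData = S4Vectors::DataFrame(cell_id = df$cell_id))
}
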