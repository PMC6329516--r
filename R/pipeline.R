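#' Write a phantom spec as a plain-text ellipsoid table
#'
#' Columns: \code{cx cy cz ax ay az rot value} (mm, radians, mm^-1), one
#' ellipsoid per line; lines starting with # are comments.
#' @param spec a \code{PhantomSpec}; @param path output path.
#' @export
writePhantomSpec <- function(spec, path) {
  lines <- c("# cx cy cz ax ay az rot value")
  for (e in spec@ellipsoids)
    lines <- c(lines, paste(format(c(e@center, e@semiAxes, e@zRotation,
                                     e@value), digits = 12, trim = TRUE),
                            collapse = " "))
  .atomicWrite(path, function(con) writeLines(lines, con))
  invisible(path)
}

#' Read a phantom spec table written by \code{writePhantomSpec}
#' @param path table path.
#' @export
readPhantomSpec <- function(path) {
  if (!file.exists(path)) .validationError(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) != 8L)
    .validationError("phantom spec needs 8 columns: cx cy cz ax ay az rot value")
  el <- lapply(seq_len(nrow(tab)), function(i) {
    r <- as.numeric(tab[i, ])
    ellipsoid(r[1:3], r[4:6], r[7], r[8])
  })
  phantomSpec(el)
}

# default run configuration values
.runDefaults <- list(
  method = "tf", lambda = 1e-3, mu = 1, levels = 2, lambda0 = 0,
  outer_iterations = 30, cg_iterations = 10, cg_tolerance = 1e-6,
  dose_i0 = 0, electronic_sigma = 0, subsample_step = 1, seed = 1,
  grid_n = "64 64 32", grid_spacing = "1 1 2", verbosity = 0
)

#' Read a run configuration file
#'
#' Flat key = value format.  Required keys: \code{geometry} (path),
#' \code{phantom} (path), \code{out_dir}.  Optional keys with defaults:
#' \code{method} (fdk|tv|tf), \code{lambda}, \code{mu}, \code{levels},
#' \code{lambda0}, \code{outer_iterations}, \code{cg_iterations},
#' \code{cg_tolerance}, \code{dose_i0} (0 = noiseless),
#' \code{electronic_sigma}, \code{subsample_step}, \code{seed},
#' \code{grid_n}, \code{grid_spacing}, \code{verbosity}.
#' @param path config path.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path) {
  kv <- .readKeyValues(path)
  for (key in c("geometry", "phantom", "out_dir"))
    if (is.null(kv[[key]]))
      .validationError(sprintf("run config %s missing key '%s'", path, key))
  cfg <- utils::modifyList(.runDefaults, kv)
  for (key in c("lambda", "mu", "lambda0", "cg_tolerance", "dose_i0",
                "electronic_sigma"))
    cfg[[key]] <- as.numeric(cfg[[key]])
  for (key in c("levels", "outer_iterations", "cg_iterations",
                "subsample_step", "seed", "verbosity"))
    cfg[[key]] <- as.integer(cfg[[key]])
  if (!cfg$method %in% c("fdk", "tv", "tf"))
    .validationError("method must be one of fdk, tv, tf")
  for (key in c("geometry", "phantom"))
    if (!file.exists(cfg[[key]]))
      .validationError(sprintf("%s file not found: %s", key, cfg[[key]]))
  cfg
}

.defaultRois <- function(grid) {
  n <- grid@n
  mid <- as.integer(n[3] %/% 2)
  c2 <- (n[1:2] - 1) / 2
  list(
    phantom = roiDisc(mid, c2, n[1] / 3, label = "phantom"),
    roi1 = roiDisc(mid, c2 + c(-n[1] / 8, 0), n[1] / 12, label = "roi1"),
    air = roiDisc(mid, c(n[1] / 16, n[2] / 16), n[1] / 20, label = "air")
  )
}

#' Run the end-to-end pipeline
#'
#' simulate -> (optionally subsample) -> reconstruct -> evaluate.  Writes the
#' reconstructed volume (NIfTI and raw float), the simulated sinogram
#' container, a metrics CSV (columns metric, roi, value, comparing the
#' reconstruction against the rasterized ground truth), a per-iteration trace
#' CSV for the iterative methods and a reproducibility manifest holding every
#' parameter plus the seed and package version.  All writes are atomic.
#' Re-running from the manifest reproduces identical outputs.
#'
#' @param config a config path or the list returned by
#'   \code{\link{readRunConfig}}.
#' @return invisibly, a list with the metrics data.frame, the
#'   \code{ReconResult}/\code{Volume}, and the output paths.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  geometry <- readGeometryConfig(cfg$geometry)
  spec <- readPhantomSpec(cfg$phantom)
  gn <- as.integer(strsplit(cfg$grid_n, "\\s+")[[1]])
  gs <- as.numeric(strsplit(cfg$grid_spacing, "\\s+")[[1]])
  grid <- volumeGrid(gn, gs)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  verbose <- cfg$verbosity > 0

  noise <- if (cfg$dose_i0 > 0)
    noiseModel(cfg$dose_i0, cfg$electronic_sigma, cfg$seed) else NULL
  sino <- simulateScan(spec, geometry, grid, noise = noise)
  if (cfg$subsample_step > 1L) sino <- subsampleViews(sino, cfg$subsample_step)
  writeSinogram(sino, file.path(outDir, "sinogram.sct"))

  truth <- rasterize(spec, grid)
  rec <- switch(cfg$method,
    fdk = fdkReconstruct(sino, grid),
    tv = tvReconstruct(sino, grid, lambda1 = cfg$lambda,
                       config = admmConfig(mu = cfg$mu,
                                           outerIterations = cfg$outer_iterations,
                                           cgIterations = cfg$cg_iterations,
                                           cgTolerance = cfg$cg_tolerance,
                                           seed = cfg$seed),
                       verbose = verbose),
    tf = admmReconstruct(sino, grid,
                         admmConfig(lambda = cfg$lambda, mu = cfg$mu,
                                    levels = cfg$levels, lambda0 = cfg$lambda0,
                                    outerIterations = cfg$outer_iterations,
                                    cgIterations = cfg$cg_iterations,
                                    cgTolerance = cfg$cg_tolerance,
                                    seed = cfg$seed),
                         verbose = verbose))
  vol <- if (is(rec, "ReconResult")) rec@volume else rec
  writeVolumeNifti(vol, file.path(outDir, "volume.nii.gz"))
  writeVolumeRaw(vol, file.path(outDir, "volume.raw"))

  if (is(rec, "ReconResult")) {
    tr <- data.frame(iteration = seq_len(rec@iterationsRun),
                     fidelity = rec@fidelityTrace,
                     objective = rec@objectiveTrace)
    .atomicWrite(file.path(outDir, "trace.csv"), function(con)
      utils::write.csv(tr, con, row.names = FALSE))
  }

  rois <- .defaultRois(grid)
  rmse <- sqrt(mean((vol@data - truth@data)^2)) /
    max(sqrt(mean(truth@data^2)), .Machine$double.eps)
  metrics <- data.frame(
    metric = c("uqi", "snr", "cnr", "rel_rmse"),
    roi = c("phantom", "roi1", "roi1_vs_air", "volume"),
    value = c(
      uqi(vol, truth, rois$phantom),
      snr(vol, rois$roi1),
      cnr(vol, rois$roi1, rois$air),
      rmse),
    stringsAsFactors = FALSE)
  metricsPath <- file.path(outDir, "metrics.csv")
  .atomicWrite(metricsPath, function(con)
    utils::write.csv(metrics, con, row.names = FALSE))

  manifest <- cfg
  manifest$package_version <- as.character(utils::packageVersion("helicalTF"))
  .atomicWrite(file.path(outDir, "manifest.txt"), function(con) {
    writeLines(vapply(names(manifest), function(k)
      sprintf("%s = %s", k, paste(manifest[[k]], collapse = " ")),
      character(1)), con)
  })

  invisible(list(metrics = metrics, result = rec,
                 paths = list(metrics = metricsPath,
                              volume = file.path(outDir, "volume.nii.gz"),
                              manifest = file.path(outDir, "manifest.txt"))))
}
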