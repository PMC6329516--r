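#' Construct a helical scan geometry
#'
#' The source travels a helix of radius \code{sourceRadius}: at view v its
#' nominal position is \code{(R cos(theta_v), R sin(theta_v), zStart + v * dz)}
#' with \code{theta_v = startAngle + v * 2*pi/viewsPerRotation} and a table
#' advance per view of \code{dz = pitch * collimation / viewsPerRotation},
#' where the collimation is the detector z-extent scaled to the isocenter.
#' A flying-focal-spot schedule adds a deterministic per-view offset to the
#' source position only (the detector stays on the gantry).
#'
#' @param sourceRadius mm isocenter-to-source.
#' @param sourceToDetector mm source-to-detector.
#' @param nRows,nChannels detector counts.
#' @param rowHeight,channelWidth mm cell sizes at the detector.
#' @param viewsPerRotation views per rotation.
#' @param nViews total views (default: one rotation).
#' @param startAngle radians.
#' @param pitch dimensionless helical pitch.
#' @param zStart source z at view 0 (mm); \code{NULL} centers the helix travel
#'   about z = 0.
#' @param ffs optional nViews x 3 per-view source offset matrix (mm); see
#'   \code{\link{ffsAlternatingZ}}.
#' @return a \code{\linkS4class{ScanGeometry}}.
#' @export
scanGeometry <- function(sourceRadius, sourceToDetector, nRows, nChannels,
                         rowHeight, channelWidth, viewsPerRotation,
                         nViews = viewsPerRotation, startAngle = 0,
                         pitch = 1, zStart = NULL, ffs = NULL) {
  nViews <- as.integer(nViews)
  if (is.null(ffs)) ffs <- matrix(0, nViews, 3L)
  ffs <- as.matrix(ffs)
  collim <- nRows * rowHeight * sourceRadius / sourceToDetector
  dz <- pitch * collim / viewsPerRotation
  if (is.null(zStart)) zStart <- -(nViews - 1) * dz / 2
  new("ScanGeometry",
      sourceRadius = as.numeric(sourceRadius),
      sourceToDetector = as.numeric(sourceToDetector),
      nRows = as.integer(nRows), nChannels = as.integer(nChannels),
      rowHeight = as.numeric(rowHeight), channelWidth = as.numeric(channelWidth),
      viewsPerRotation = as.integer(viewsPerRotation), nViews = nViews,
      startAngle = as.numeric(startAngle), pitch = as.numeric(pitch),
      zStart = as.numeric(zStart), ffs = ffs)
}

#' Total collimation at the isocenter (mm)
#' @param geometry a \code{ScanGeometry}.
#' @export
collimation <- function(geometry) {
  geometry@nRows * geometry@rowHeight *
    geometry@sourceRadius / geometry@sourceToDetector
}

#' Table advance per view (mm)
#' @param geometry a \code{ScanGeometry}.
#' @export
zPerView <- function(geometry) {
  geometry@pitch * collimation(geometry) / geometry@viewsPerRotation
}

#' Angular step between views (radians)
#' @param geometry a \code{ScanGeometry}.
#' @export
angularStep <- function(geometry) 2 * pi / geometry@viewsPerRotation

#' Alternating z flying-focal-spot schedule
#'
#' Builds the per-view offset table for a z flying focal spot that deflects
#' the source by +deltaZ on even views and -deltaZ on odd views (the usual
#' doubled z sampling pattern).
#' @param nViews number of views.
#' @param deltaZ mm deflection amplitude.
#' @return nViews x 3 offset matrix usable as the \code{ffs} argument of
#'   \code{\link{scanGeometry}}.
#' @export
ffsAlternatingZ <- function(nViews, deltaZ) {
  ffs <- matrix(0, nViews, 3L)
  ffs[, 3] <- ifelse(seq_len(nViews) %% 2 == 1, deltaZ, -deltaZ)
  ffs
}

#' Source and detector pose at one view
#'
#' @param geometry a \code{ScanGeometry}.
#' @param view 0-based view index.
#' @return list with \code{source} (mm, including any flying-focal-spot
#'   offset), \code{detCenter}, orthonormal detector axes \code{channelDir},
#'   \code{rowDir} and the central-ray unit vector \code{normal}.
#' @export
sourcePose <- function(geometry, view) {
  if (view < 0 || view >= geometry@nViews)
    .validationError(sprintf("view %d out of range [0, %d)",
                             view, geometry@nViews))
  p <- .poseMatrices(geometry)
  v <- view + 1L
  lapply(list(source = p$src[v, ], detCenter = p$detC[v, ],
              channelDir = p$eu[v, ], rowDir = p$ev[v, ],
              normal = p$ehat[v, ]), unname)
}

# per-view pose matrices (nViews x 3 each) shared by the projectors
.poseMatrices <- function(geometry) {
  v <- seq_len(geometry@nViews) - 1
  theta <- geometry@startAngle + v * angularStep(geometry)
  z <- geometry@zStart + v * zPerView(geometry)
  R <- geometry@sourceRadius
  s0 <- cbind(R * cos(theta), R * sin(theta), z)
  ehat <- cbind(-cos(theta), -sin(theta), 0)
  eu <- cbind(-sin(theta), cos(theta), 0)
  ev <- cbind(0, 0, rep(1, length(theta)))
  list(src = s0 + geometry@ffs,
       detC = s0 + geometry@sourceToDetector * ehat,
       eu = eu, ev = ev, ehat = ehat)
}

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(paste0(
    "ScanGeometry: R = %g mm, SDD = %g mm, %d rows x %d channels\n",
    "  %d views (%d per rotation), pitch %g, collimation %g mm at iso, ffs %s\n"),
    object@sourceRadius, object@sourceToDetector, object@nRows,
    object@nChannels, object@nViews, object@viewsPerRotation, object@pitch,
    collimation(object), if (any(object@ffs != 0)) "on" else "off"))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram %d x %d x %d, range [%.4g, %.4g]\n",
              dim(object@data)[1], dim(object@data)[2], dim(object@data)[3],
              min(object@data), max(object@data)))
})

#' Construct a Sinogram
#' @param data nViews x nRows x nChannels array.
#' @param geometry matching \code{ScanGeometry}.
#' @export
sinogram <- function(data, geometry) new("Sinogram", data = data,
                                         geometry = geometry)

#' @describeIn sinogram projection values as a plain array
#' @param x a \code{Sinogram}.
#' @export
sinoData <- function(x) x@data

#' @describeIn sinogram the geometry a sinogram was measured under
#' @export
scanGeometryOf <- function(x) x@geometry

#' Write a scan geometry as a flat key-value config file
#'
#' Keys follow the field names \code{source_radius}, \code{source_to_detector},
#' \code{n_rows}, \code{n_channels}, \code{row_height}, \code{channel_width},
#' \code{views_per_rotation}, \code{n_views}, \code{start_angle}, \code{pitch},
#' \code{z_start} and \code{ffs_schedule} (\code{none}, or semicolon-separated
#' \code{x:y:z} mm triples, one per view).
#' @param geometry a \code{ScanGeometry}; @param path output file.
#' @export
writeGeometryConfig <- function(geometry, path) {
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  ffs <- if (all(geometry@ffs == 0)) "none" else
    paste(apply(geometry@ffs, 1, function(r) paste(fmt(r), collapse = ":")),
          collapse = ";")
  lines <- c(
    sprintf("source_radius = %s", fmt(geometry@sourceRadius)),
    sprintf("source_to_detector = %s", fmt(geometry@sourceToDetector)),
    sprintf("n_rows = %d", geometry@nRows),
    sprintf("n_channels = %d", geometry@nChannels),
    sprintf("row_height = %s", fmt(geometry@rowHeight)),
    sprintf("channel_width = %s", fmt(geometry@channelWidth)),
    sprintf("views_per_rotation = %d", geometry@viewsPerRotation),
    sprintf("n_views = %d", geometry@nViews),
    sprintf("start_angle = %s", fmt(geometry@startAngle)),
    sprintf("pitch = %s", fmt(geometry@pitch)),
    sprintf("z_start = %s", fmt(geometry@zStart)),
    sprintf("ffs_schedule = %s", ffs)
  )
  .atomicWrite(path, function(con) writeLines(lines, con))
  invisible(path)
}

#' Read a scan geometry config written by \code{writeGeometryConfig}
#' @param path config file path.
#' @export
readGeometryConfig <- function(path) {
  kv <- .readKeyValues(path)
  need <- c("source_radius", "source_to_detector", "n_rows", "n_channels",
            "row_height", "channel_width", "views_per_rotation", "n_views",
            "start_angle", "pitch", "z_start")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    .validationError(sprintf("geometry config %s missing keys: %s", path,
                             paste(miss, collapse = ", ")))
  nViews <- as.integer(kv$n_views)
  ffs <- NULL
  if (!is.null(kv$ffs_schedule) && kv$ffs_schedule != "none") {
    rows <- strsplit(strsplit(kv$ffs_schedule, ";")[[1]], ":")
    ffs <- do.call(rbind, lapply(rows, as.numeric))
    if (nrow(ffs) != nViews)
      .validationError("ffs_schedule length does not match n_views")
  }
  scanGeometry(as.numeric(kv$source_radius), as.numeric(kv$source_to_detector),
               as.integer(kv$n_rows), as.integer(kv$n_channels),
               as.numeric(kv$row_height), as.numeric(kv$channel_width),
               as.integer(kv$views_per_rotation), nViews,
               as.numeric(kv$start_angle), as.numeric(kv$pitch),
               as.numeric(kv$z_start), ffs)
}
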