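# Atomic write: write to a temp file in the same directory, then rename, so
# interrupted runs never leave truncated outputs.
.atomicWrite <- function(path, writer, binary = FALSE) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), pattern = ".partial_")
  con <- if (binary) file(tmp, "wb") else file(tmp, "w")
  ok <- FALSE
  tryCatch({
    writer(con)
    close(con)
    ok <- TRUE
  }, finally = {
    if (!ok) {
      try(close(con), silent = TRUE)
      unlink(tmp)
    }
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop(sprintf("could not move output into place at %s", path))
  }
  invisible(path)
}

# flat "key = value" reader shared by geometry/run configs and manifests
.readKeyValues <- function(path) {
  if (!file.exists(path))
    .validationError(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

# --- flat dataset container -------------------------------------------------
# Self-describing single-file container: a plain-text header (attributes and a
# dataset table: name, dims, byte offset) terminated by an @data line, then the
# concatenated little-endian float32 payloads.

.writeContainer <- function(path, datasets, attrs = list()) {
  hdr <- c("helicalTF-container 1")
  for (k in names(attrs))
    hdr <- c(hdr, sprintf("attr %s = %s", k,
                          paste(format(attrs[[k]], digits = 15, trim = TRUE),
                                collapse = " ")))
  off <- 0
  for (nm in names(datasets)) {
    d <- dim(datasets[[nm]])
    if (is.null(d)) d <- length(datasets[[nm]])
    hdr <- c(hdr, sprintf("dataset %s dims %s offset %d", nm,
                          paste(d, collapse = " "), off))
    off <- off + 4 * prod(d)
  }
  hdr <- c(hdr, "@data")
  .atomicWrite(path, function(con) {
    writeLines(hdr, con)
    for (nm in names(datasets))
      writeBin(as.vector(as.numeric(datasets[[nm]])), con, size = 4L,
               endian = "little")
  }, binary = TRUE)
}

.readContainer <- function(path) {
  if (!file.exists(path)) .validationError(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) .validationError(sprintf("truncated container: %s", path))
    if (ln == "@data") break
    hdr <- c(hdr, ln)
  }
  if (!length(hdr) || !startsWith(hdr[1], "helicalTF-container"))
    .validationError(sprintf("not a helicalTF container: %s", path))
  attrs <- list(); dsets <- list()
  for (ln in hdr[-1]) {
    if (startsWith(ln, "attr ")) {
      m <- regmatches(ln, regexec("^attr (\\S+) = (.*)$", ln))[[1]]
      attrs[[m[2]]] <- m[3]
    } else if (startsWith(ln, "dataset ")) {
      m <- regmatches(ln, regexec("^dataset (\\S+) dims ([0-9 ]+) offset (\\d+)$",
                                  ln))[[1]]
      dsets[[m[2]]] <- list(dims = as.integer(strsplit(m[3], " ")[[1]]))
    }
  }
  data <- list()
  for (nm in names(dsets)) {
    d <- dsets[[nm]]$dims
    v <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
    data[[nm]] <- if (length(d) > 1L) array(v, dim = d) else v
  }
  list(attrs = attrs, datasets = data)
}

#' Write a sinogram container
#'
#' Single-file container holding dataset \code{projections}
#' (nViews x nRows x nChannels, 32-bit float) plus every geometry field as a
#' named attribute, so the file is self-describing.
#' @param sino a \code{\linkS4class{Sinogram}}; @param path output path.
#' @export
writeSinogram <- function(sino, path) {
  g <- sino@geometry
  ffs <- if (all(g@ffs == 0)) "none" else
    paste(apply(g@ffs, 1, function(r)
      paste(format(r, digits = 15, trim = TRUE), collapse = ":")),
      collapse = ";")
  attrs <- list(
    source_radius = g@sourceRadius, source_to_detector = g@sourceToDetector,
    n_rows = g@nRows, n_channels = g@nChannels,
    row_height = g@rowHeight, channel_width = g@channelWidth,
    views_per_rotation = g@viewsPerRotation, n_views = g@nViews,
    start_angle = g@startAngle, pitch = g@pitch, z_start = g@zStart,
    ffs_schedule = ffs)
  .writeContainer(path, list(projections = sino@data), attrs)
  invisible(path)
}

#' Read a sinogram container written by \code{writeSinogram}
#' @param path container path.
#' @export
readSinogram <- function(path) {
  ct <- .readContainer(path)
  a <- ct$attrs
  ffs <- NULL
  if (!is.null(a$ffs_schedule) && a$ffs_schedule != "none") {
    rows <- strsplit(strsplit(a$ffs_schedule, ";")[[1]], ":")
    ffs <- do.call(rbind, lapply(rows, as.numeric))
  }
  g <- scanGeometry(as.numeric(a$source_radius), as.numeric(a$source_to_detector),
                    as.integer(a$n_rows), as.integer(a$n_channels),
                    as.numeric(a$row_height), as.numeric(a$channel_width),
                    as.integer(a$views_per_rotation), as.integer(a$n_views),
                    as.numeric(a$start_angle), as.numeric(a$pitch),
                    as.numeric(a$z_start), ffs)
  sinogram(ct$datasets$projections, g)
}

#' Write framelet coefficients to a container
#'
#' One dataset per level/band/axis named \code{L<l>_B<j>_<axis>} plus
#' \code{lowpass_<axis>}.
#' @param coeffs a \code{\linkS4class{FrameletCoeffs}}; @param path output path.
#' @export
writeFrameletCoeffs <- function(coeffs, path) {
  ds <- list()
  for (l in seq_len(coeffs@levels))
    for (j in 1:2)
      for (ax in c("x", "y", "z"))
        ds[[sprintf("L%d_B%d_%s", l, j, ax)]] <-
          coeffs@bands[[l]][[paste0("B", j)]][[ax]]
  for (ax in c("x", "y", "z"))
    ds[[paste0("lowpass_", ax)]] <- coeffs@lowpass[[ax]]
  .writeContainer(path, ds, list(levels = coeffs@levels,
                                 dims = coeffs@dims))
  invisible(path)
}

#' Read framelet coefficients written by \code{writeFrameletCoeffs}
#' @param path container path.
#' @export
readFrameletCoeffs <- function(path) {
  ct <- .readContainer(path)
  L <- as.integer(ct$attrs$levels)
  dims <- as.integer(strsplit(ct$attrs$dims, " ")[[1]])
  bands <- vector("list", L)
  for (l in seq_len(L)) {
    bands[[l]] <- list(
      B1 = list(x = ct$datasets[[sprintf("L%d_B1_x", l)]],
                y = ct$datasets[[sprintf("L%d_B1_y", l)]],
                z = ct$datasets[[sprintf("L%d_B1_z", l)]]),
      B2 = list(x = ct$datasets[[sprintf("L%d_B2_x", l)]],
                y = ct$datasets[[sprintf("L%d_B2_y", l)]],
                z = ct$datasets[[sprintf("L%d_B2_z", l)]]))
  }
  lowpass <- list(x = ct$datasets$lowpass_x, y = ct$datasets$lowpass_y,
                  z = ct$datasets$lowpass_z)
  new("FrameletCoeffs", dims = dims, levels = L, bands = bands,
      lowpass = lowpass)
}
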