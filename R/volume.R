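#' Construct a voxel grid
#'
#' @param n voxel counts (length 3, or a scalar reused for all axes).
#' @param spacing mm per voxel (length 3 or scalar).
#' @param origin mm offset of the grid center from the isocenter.
#' @return a \code{\linkS4class{VolumeGrid}}.
#' @examples
#' g <- volumeGrid(c(64, 64, 32), spacing = c(1, 1, 2))
#' @export
volumeGrid <- function(n, spacing = 1, origin = c(0, 0, 0)) {
  n <- as.integer(rep_len(n, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  new("VolumeGrid", n = n, spacing = spacing, origin = origin)
}

#' Wrap a 3D array as a Volume
#'
#' @param data 3D numeric array (or scalar 0 for an empty volume).
#' @param grid the \code{\linkS4class{VolumeGrid}}.
#' @export
volume <- function(data, grid) {
  if (length(data) == 1L) data <- array(as.numeric(data), dim = grid@n)
  if (is.null(dim(data))) .validationError("volume data must be a 3D array")
  new("Volume", data = array(as.numeric(data), dim = dim(data)), grid = grid)
}

#' @describeIn volume voxel data as a plain 3D array
#' @param x a \code{Volume}.
#' @export
voxelData <- function(x) x@data

#' @describeIn volume the grid of a Volume
#' @export
volumeGridOf <- function(x) x@grid

#' Voxel-center coordinates along one axis
#'
#' @param grid a \code{VolumeGrid}; @param axis 1, 2 or 3.
#' @return mm positions of the voxel centers (0-based index order).
#' @export
axisCoords <- function(grid, axis) {
  n <- grid@n[axis]
  grid@origin[axis] + (seq_len(n) - 1 - (n - 1) / 2) * grid@spacing[axis]
}

# mm position of voxel (0,0,0) center, used by the C++ kernels
.lowCorner <- function(grid) {
  grid@origin - (grid@n - 1) / 2 * grid@spacing
}

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              object@n[1], object@n[2], object@n[3],
              paste(signif(object@spacing, 4), collapse = " x "),
              paste(signif(object@origin, 4), collapse = ", ")))
})

setMethod("show", "Volume", function(object) {
  d <- object@data
  cat(sprintf("Volume %d x %d x %d, range [%.4g, %.4g] mm^-1\n",
              dim(d)[1], dim(d)[2], dim(d)[3], min(d), max(d)))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult: %d outer iterations, final objective %.6g\n",
              object@iterationsRun,
              utils::tail(object@objectiveTrace, 1)))
  show(object@volume)
})

#' @describeIn volume reconstructed volume of a ReconResult
#' @export
reconVolume <- function(x) x@volume

#' @describeIn volume objective trace of a ReconResult
#' @export
objectiveTrace <- function(x) x@objectiveTrace

#' @describeIn volume data-fidelity trace of a ReconResult
#' @export
fidelityTrace <- function(x) x@fidelityTrace

#' Write a volume as raw 32-bit floats with a text sidecar header
#'
#' The payload file holds the voxels in column-major (x fastest) order as
#' little-endian float32; \code{<path>.hdr} records dims, spacing and origin
#' as flat key = value lines.
#' @param vol a \code{Volume}; @param path output path for the payload.
#' @export
writeVolumeRaw <- function(vol, path) {
  .atomicWrite(path, function(con) {
    writeBin(as.vector(vol@data), con, size = 4L, endian = "little")
  }, binary = TRUE)
  hdr <- c(
    sprintf("dims = %s", paste(vol@grid@n, collapse = " ")),
    sprintf("spacing = %s", paste(format(vol@grid@spacing, digits = 12),
                                  collapse = " ")),
    sprintf("origin = %s", paste(format(vol@grid@origin, digits = 12),
                                 collapse = " ")),
    "dtype = float32le"
  )
  .atomicWrite(paste0(path, ".hdr"), function(con) {
    writeLines(hdr, con)
  })
  invisible(path)
}

#' Read a raw-float volume written by \code{writeVolumeRaw}
#' @param path payload path (expects \code{<path>.hdr} alongside).
#' @export
readVolumeRaw <- function(path) {
  hdr <- .readKeyValues(paste0(path, ".hdr"))
  n <- as.integer(strsplit(hdr$dims, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$spacing, "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$origin, "\\s+")[[1]])
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = prod(n), size = 4L, endian = "little")
  volume(array(v, dim = n), volumeGrid(n, spacing, origin))
}

#' Write a volume as NIfTI
#'
#' Spacing is carried in the NIfTI header (mm).
#' @param vol a \code{Volume}; @param path output path (.nii or .nii.gz).
#' @export
writeVolumeNifti <- function(vol, path) {
  img <- RNifti::asNifti(vol@data, reference = NULL)
  img <- RNifti::`pixdim<-`(img, vol@grid@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a Volume
#' @param path NIfTI path; @param origin optional grid-center offset (mm).
#' @export
readVolumeNifti <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  volume(array(as.numeric(img), dim = dim(img)),
         volumeGrid(dim(img), sp, origin))
}
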