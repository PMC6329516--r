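#' Forward projection (the system operator A)
#'
#' Computes the line integral of the volume along the single ray from the
#' (possibly flying-focal-spot offset) source to each detector cell center,
#' using Joseph's method: the ray is stepped across the slices of its driving
#' axis and the volume is bilinearly interpolated within each slice.  The
#' operator is linear in the volume and rays that miss the grid contribute 0.
#'
#' @param vol a \code{\linkS4class{Volume}}.
#' @param geometry a \code{\linkS4class{ScanGeometry}}.
#' @return a \code{\linkS4class{Sinogram}}.
#' @seealso \code{\link{backProject}} for the exact numerical adjoint.
#' @export
forwardProject <- function(vol, geometry) {
  if (any(!is.finite(vol@data)))
    .validationError("volume contains non-finite voxel values")
  p <- .poseMatrices(geometry)
  s <- .cppForwardProject(as.vector(vol@data), vol@grid@n, vol@grid@spacing,
                          .lowCorner(vol@grid), p$src, p$detC, p$eu, p$ev,
                          geometry@nRows, geometry@nChannels,
                          geometry@rowHeight, geometry@channelWidth)
  sinogram(s, geometry)
}

#' Backprojection (the adjoint operator A^T)
#'
#' Implements the exact numerical transpose of \code{\link{forwardProject}}:
#' the same Joseph interpolation weights, scattered instead of gathered, so
#' that \code{<Ax, y> == <x, A^T y>} to rounding error.
#'
#' @param sino a \code{\linkS4class{Sinogram}}.
#' @param grid the target \code{\linkS4class{VolumeGrid}}.
#' @return a \code{\linkS4class{Volume}}.
#' @export
backProject <- function(sino, grid) {
  if (any(!is.finite(sino@data)))
    .validationError("sinogram contains non-finite values")
  g <- sino@geometry
  p <- .poseMatrices(g)
  v <- .cppBackProject(as.vector(sino@data), grid@n, grid@spacing,
                       .lowCorner(grid), p$src, p$detC, p$eu, p$ev,
                       g@nRows, g@nChannels, g@rowHeight, g@channelWidth)
  volume(v, grid)
}
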