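#' @import methods
NULL

.validationError <- function(msg) {
  stop(structure(
    class = c("helicalTF_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

.solverError <- function(msg) {
  stop(structure(
    class = c("helicalTF_solver_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

.undefinedMetric <- function(msg) {
  stop(structure(
    class = c("helicalTF_undefined_metric", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Regular voxel lattice for a 3D image volume
#'
#' A \code{VolumeGrid} describes the sampling of a reconstruction volume:
#' voxel counts, physical spacing (mm) and the offset of the grid center from
#' the isocenter (the rotation axis runs along z through x = y = 0).  Voxel
#' indices are 0-based and voxel \code{(i,j,k)} is centered at
#' \code{origin + (i - (n-1)/2) * spacing} per axis.
#'
#' @slot n integer(3), voxel counts along x, y, z.
#' @slot spacing numeric(3), mm per voxel along x, y, z.
#' @slot origin numeric(3), mm offset of the grid center from the isocenter.
#' @export
setClass("VolumeGrid",
  representation(n = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(object@n) != 3L || any(object@n < 1L))
      return("n must be three counts >= 1")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be three positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be three finite values (mm)")
    TRUE
  }
)

#' A 3D image volume on a regular grid
#'
#' @slot data 3D numeric array of attenuation values (mm^-1), dims match the grid.
#' @slot grid the \code{\linkS4class{VolumeGrid}}.
#' @export
setClass("Volume",
  representation(data = "array", grid = "VolumeGrid"),
  validity = function(object) {
    if (!identical(dim(object@data), as.integer(object@grid@n)))
      return("data dims do not match grid voxel counts")
    TRUE
  }
)

#' Helical cone-beam scan geometry
#'
#' Source/detector model for a multi-row helical scan with an optional flying
#' focal spot.  The source rotates counter-clockwise from +x while the table
#' (equivalently the source-detector pair) advances along z; the flat
#' equispaced detector panel is rigidly attached to the gantry, centered on
#' the ray from the nominal source position through the isocenter.
#'
#' @slot sourceRadius mm, isocenter-to-source distance.
#' @slot sourceToDetector mm, source-to-detector distance.
#' @slot nRows,nChannels detector grid counts (rows along z, channels transverse).
#' @slot rowHeight,channelWidth mm cell sizes at the detector.
#' @slot viewsPerRotation views per full 2*pi rotation.
#' @slot nViews total number of views.
#' @slot startAngle radians, source angle of view 0.
#' @slot pitch dimensionless helical pitch: table feed per rotation divided by
#'   the total collimation (nRows * rowHeight scaled to the isocenter).
#' @slot zStart mm, source z position at view 0.
#' @slot ffs nViews x 3 matrix of per-view source offsets (mm), all-zero when
#'   the flying focal spot is off.
#' @export
setClass("ScanGeometry",
  representation(
    sourceRadius = "numeric", sourceToDetector = "numeric",
    nRows = "integer", nChannels = "integer",
    rowHeight = "numeric", channelWidth = "numeric",
    viewsPerRotation = "integer", nViews = "integer",
    startAngle = "numeric", pitch = "numeric",
    zStart = "numeric", ffs = "matrix"
  ),
  validity = function(object) {
    if (object@sourceRadius <= 0 || object@sourceToDetector <= object@sourceRadius)
      return("need 0 < sourceRadius < sourceToDetector")
    if (object@nRows < 1L || object@nChannels < 1L)
      return("detector counts must be >= 1")
    if (object@rowHeight <= 0 || object@channelWidth <= 0)
      return("detector cell sizes must be positive")
    if (object@viewsPerRotation < 1L || object@nViews < 1L)
      return("view counts must be >= 1")
    if (object@pitch <= 0)
      return("pitch must be strictly positive")
    if (!identical(dim(object@ffs), c(as.integer(object@nViews), 3L)))
      return("ffs must be an nViews x 3 offset matrix")
    if (any(!is.finite(object@ffs)))
      return("ffs offsets must be finite")
    TRUE
  }
)

#' Helical projection data
#'
#' Line integrals (dimensionless) on the detector, one value per
#' (view, row, channel), together with the geometry they were measured under.
#'
#' @slot data numeric array, nViews x nRows x nChannels.
#' @slot geometry the \code{\linkS4class{ScanGeometry}}.
#' @export
setClass("Sinogram",
  representation(data = "array", geometry = "ScanGeometry"),
  validity = function(object) {
    g <- object@geometry
    want <- c(g@nViews, g@nRows, g@nChannels)
    if (!identical(dim(object@data), as.integer(want)))
      return(sprintf("data dims must be %s", paste(want, collapse = " x ")))
    if (any(!is.finite(object@data)))
      return("sinogram values must be finite")
    TRUE
  }
)

#' Tensor-framelet coefficients
#'
#' The transform-domain object W x.  Per level l = 1..L and band j = 1
#' (first difference) or 2 (second difference) there are three full-grid
#' sub-volumes, one per axis, each scaled by 1/sqrt(3); the final lowpass is
#' likewise stored as a per-axis triple (the transform filters each axis
#' unfolding independently, which is what makes the frame tight).  For L = 1
#' the lowpass triple is exactly the averaging (j = 0) band of the uni-level
#' transform.
#'
#' @slot dims integer(3), grid dims of every sub-volume.
#' @slot levels integer, number of levels L.
#' @slot bands list of length L; element l is
#'   \code{list(B1 = list(x=,y=,z=), B2 = list(x=,y=,z=))}.
#' @slot lowpass \code{list(x=,y=,z=)} final per-axis lowpass coefficients.
#' @export
setClass("FrameletCoeffs",
  representation(dims = "integer", levels = "integer", bands = "list",
                 lowpass = "list"),
  validity = function(object) {
    L <- object@levels
    if (L < 1L) return("levels must be >= 1")
    if (length(object@bands) != L) return("bands list must have L elements")
    ok <- function(tri) {
      is.list(tri) && all(c("x", "y", "z") %in% names(tri)) &&
        all(vapply(tri[c("x", "y", "z")],
                   function(a) identical(dim(a), object@dims), logical(1)))
    }
    for (l in seq_len(L)) {
      el <- object@bands[[l]]
      if (!is.list(el) || !all(c("B1", "B2") %in% names(el)))
        return("each level needs bands B1 and B2")
      if (!ok(el$B1) || !ok(el$B2))
        return("band sub-volumes must all match the grid dims")
    }
    if (!ok(object@lowpass)) return("lowpass triple must match the grid dims")
    TRUE
  }
)

#' Regularization weights for the tensor-framelet norm
#'
#' @slot lambda L x 2 matrix of non-negative weights, column j for band j.
#' @slot lambda0 non-negative weight on the final lowpass term.
#' @export
setClass("RegWeights",
  representation(lambda = "matrix", lambda0 = "numeric"),
  validity = function(object) {
    if (ncol(object@lambda) != 2L) return("lambda must be an L x 2 matrix")
    if (any(object@lambda < 0) || object@lambda0 < 0)
      return("weights must be non-negative")
    TRUE
  }
)

#' ADMM solver configuration
#'
#' @slot weights \code{\linkS4class{RegWeights}}.
#' @slot mu augmented-Lagrangian parameter, > 0.
#' @slot levels framelet levels L.
#' @slot outerIterations number of outer ADMM iterations.
#' @slot cgIterations,cgTolerance inner conjugate-gradient budget.
#' @slot init "zero" or "fdk" initialization of the volume iterate.
#' @slot relTolerance early-stop threshold on the relative iterate change
#'   (0 disables early stopping).
#' @slot seed integer seed recorded for reproducibility manifests.
#' @export
setClass("ADMMConfig",
  representation(
    weights = "RegWeights", mu = "numeric", levels = "integer",
    outerIterations = "integer", cgIterations = "integer",
    cgTolerance = "numeric", init = "character", relTolerance = "numeric",
    seed = "integer"
  ),
  validity = function(object) {
    if (object@mu <= 0) return("mu must be > 0")
    if (object@outerIterations < 1L || object@cgIterations < 1L)
      return("iteration counts must be >= 1")
    if (object@cgTolerance <= 0) return("cgTolerance must be > 0")
    if (!object@init %in% c("zero", "fdk"))
      return("init must be 'zero' or 'fdk'")
    if (nrow(object@weights@lambda) != object@levels)
      return("weights lambda must have one row per level")
    TRUE
  }
)

#' Reconstruction result
#'
#' @slot volume the reconstructed \code{\linkS4class{Volume}}.
#' @slot objectiveTrace per-outer-iteration objective
#'   0.5*||Ax - y||^2 + ||Wx||_{1,lambda} (on the normalized data scale).
#' @slot fidelityTrace per-outer-iteration 0.5*||Ax - y||^2.
#' @slot iterationsRun number of outer iterations performed.
#' @export
setClass("ReconResult",
  representation(volume = "Volume", objectiveTrace = "numeric",
                 fidelityTrace = "numeric", iterationsRun = "integer"),
  validity = function(object) {
    if (length(object@objectiveTrace) != object@iterationsRun ||
        length(object@fidelityTrace) != object@iterationsRun)
      return("traces must have length iterationsRun")
    if (any(!is.finite(object@objectiveTrace)) ||
        any(!is.finite(object@fidelityTrace)))
      return("traces must be finite")
    TRUE
  }
)

#' Analytic ellipsoid for phantom construction
#'
#' @slot center mm(3); @slot semiAxes mm(3); @slot zRotation radians about z;
#' @slot value additive attenuation (mm^-1), may be negative inside a
#'   positive background.
#' @export
setClass("EllipsoidSpec",
  representation(center = "numeric", semiAxes = "numeric",
                 zRotation = "numeric", value = "numeric"),
  validity = function(object) {
    if (length(object@center) != 3L || length(object@semiAxes) != 3L)
      return("center and semiAxes must each have 3 components")
    if (any(object@semiAxes <= 0)) return("semi-axes must be positive")
    TRUE
  }
)

#' Composite analytic phantom
#'
#' A list of additive ellipsoids.  The composite attenuation must be
#' non-negative everywhere (checked at rasterization).
#' @slot ellipsoids list of \code{\linkS4class{EllipsoidSpec}}.
#' @export
setClass("PhantomSpec",
  representation(ellipsoids = "list"),
  validity = function(object) {
    if (!all(vapply(object@ellipsoids, is, logical(1), "EllipsoidSpec")))
      return("all members must be EllipsoidSpec")
    TRUE
  }
)

#' Poisson transmission noise model
#'
#' Dose is parameterized by the incident photon count per detector cell.
#' @slot i0 incident photons per cell (> 0).
#' @slot sigma optional Gaussian electronic noise (counts), >= 0.
#' @slot seed integer RNG seed.
#' @export
setClass("NoiseModel",
  representation(i0 = "numeric", sigma = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@i0 <= 0) return("i0 must be > 0")
    if (object@sigma < 0) return("sigma must be >= 0")
    TRUE
  }
)

#' Region of interest
#'
#' Either an explicit voxel mask or an in-slice disc (slice index, center,
#' radius, all in 0-based voxel units).
#' @slot type "mask" or "disc".
#' @slot mask logical array (for type "mask").
#' @slot slice,center,radius disc description (for type "disc").
#' @slot label character label used in metric tables.
#' @export
setClass("ROISpec",
  representation(type = "character", mask = "array", slice = "integer",
                 center = "numeric", radius = "numeric", label = "character"),
  validity = function(object) {
    if (!object@type %in% c("mask", "disc")) return("type must be mask or disc")
    if (object@type == "disc" && object@radius <= 0)
      return("disc radius must be positive")
    TRUE
  }
)

#' In-slice line profile for edge/MTF analysis
#'
#' @slot slice 0-based z slice index.
#' @slot start,end 0-based in-plane (x, y) voxel coordinates.
#' @slot nSamples number of samples along the segment (>= 16).
#' @export
setClass("LineProfile",
  representation(slice = "integer", start = "numeric", end = "numeric",
                 nSamples = "integer"),
  validity = function(object) {
    if (object@nSamples < 16L) return("nSamples must be >= 16")
    if (length(object@start) != 2L || length(object@end) != 2L)
      return("start and end must be in-plane (x, y) pairs")
    if (all(object@start == object@end)) return("degenerate profile")
    TRUE
  }
)
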