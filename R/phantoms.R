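#' Ellipsoid phantom member
#'
#' @param center mm(3); @param semiAxes mm(3); @param zRotation radians about
#'   the z axis; @param value additive attenuation (mm^-1).
#' @return an \code{\linkS4class{EllipsoidSpec}}.
#' @export
ellipsoid <- function(center, semiAxes, zRotation = 0, value = 0.02) {
  new("EllipsoidSpec", center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), zRotation = as.numeric(zRotation),
      value = as.numeric(value))
}

#' Composite phantom from ellipsoids
#' @param ... \code{EllipsoidSpec} objects (or a single list of them).
#' @export
phantomSpec <- function(...) {
  el <- list(...)
  if (length(el) == 1L && is.list(el[[1]]) && !is(el[[1]], "EllipsoidSpec"))
    el <- el[[1]]
  new("PhantomSpec", ellipsoids = el)
}

#' Two-ellipsoid test phantom
#'
#' A water-like outer ellipsoid with a denser inner inclusion, the standard
#' piecewise-constant recovery target for solver tests.  Sized for the
#' desk-scale grid (about 64 mm across).
#' @param scale spatial scale factor (1 fits the desk preset).
#' @export
twoEllipsoidPhantom <- function(scale = 1) {
  phantomSpec(
    ellipsoid(c(0, 0, 0) * scale, c(22, 17, 24) * scale, 0, 0.02),
    ellipsoid(c(6, -3, 4) * scale, c(8, 6, 9) * scale, 0.4, 0.01)
  )
}

#' ACR-like cylindrical phantom
#'
#' Emulates the layout of a cylindrical accreditation phantom at desk scale:
#' a water cylinder, three low-contrast insert rods, an air pocket and one
#' high-contrast block providing a sharp edge for MTF measurement.  Cylinders
#' are ellipsoids with long z semi-axes.
#' @param radius mm cylinder radius; @param height mm cylinder height.
#' @export
acrPhantom <- function(radius = 24, height = 56) {
  hz <- height / 2
  phantomSpec(
    ellipsoid(c(0, 0, 0), c(radius, radius, hz), 0, 0.02),            # water body
    ellipsoid(c(-radius / 2, 0, 0), c(3, 3, hz), 0, 0.010),           # rod 1
    ellipsoid(c(radius / 2, 0, 0), c(3, 3, hz), 0, 0.005),            # rod 2
    ellipsoid(c(0, radius / 2, 0), c(3, 3, hz), 0, -0.010),           # rod 3 (lower)
    ellipsoid(c(0, -radius / 2, 0), c(3, 3, hz), 0, -0.02),           # air pocket
    ellipsoid(c(-radius / 4, -radius / 4, 0), c(5, 5, hz), 0, 0.025)  # edge block
  )
}

#' Poisson transmission noise model
#'
#' @param i0 incident photons per detector cell (dose proxy).  The presets
#'   \code{dosePreset} map the four tube-voltage labels onto photon counts.
#' @param sigma Gaussian electronic noise (counts).
#' @param seed RNG seed.
#' @export
noiseModel <- function(i0 = 1e5, sigma = 0, seed = 1L) {
  new("NoiseModel", i0 = as.numeric(i0), sigma = as.numeric(sigma),
      seed = as.integer(seed))
}

#' Dose presets labelled by tube voltage
#'
#' Photon-count stand-ins for the 80/100/120/140 kV dose levels; dose here is
#' modeled purely as incident photons per cell.
#' @param kv one of 80, 100, 120, 140.
#' @export
dosePreset <- function(kv = 100) {
  tab <- c("80" = 5e4, "100" = 1e5, "120" = 2e5, "140" = 4e5)
  key <- as.character(kv)
  if (!key %in% names(tab)) .validationError("kv must be 80, 100, 120 or 140")
  unname(tab[key])
}

#' Rasterize an analytic phantom onto a grid
#'
#' Voxel value = sum of the member attenuations at the voxel center
#' (optionally supersampled per axis and averaged).  Deterministic.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @param grid a \code{\linkS4class{VolumeGrid}}.
#' @param supersample samples per axis per voxel (1 = voxel centers).
#' @return a \code{\linkS4class{Volume}}.
#' @export
rasterize <- function(spec, grid, supersample = 1L) {
  acc <- array(0, dim = grid@n)
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  cx <- axisCoords(grid, 1); cy <- axisCoords(grid, 2); cz <- axisCoords(grid, 3)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    px <- cx + ox * grid@spacing[1]
    py <- cy + oy * grid@spacing[2]
    pz <- cz + oz * grid@spacing[3]
    sub <- array(0, dim = grid@n)
    for (e in spec@ellipsoids) {
      dx <- px - e@center[1]
      dy <- py - e@center[2]
      dz <- pz - e@center[3]
      co <- cos(e@zRotation); si <- sin(e@zRotation)
      # rotate into the ellipsoid frame (separable outer products keep it fast)
      u <- outer(dx * co, dy * si, `+`)   # nx x ny
      w <- outer(-dx * si, dy * co, `+`)
      q2 <- (u / e@semiAxes[1])^2 + (w / e@semiAxes[2])^2
      inPlane <- array(rep(q2, length(dz)), dim = grid@n)
      zTerm <- rep((dz / e@semiAxes[3])^2, each = length(px) * length(py))
      sub <- sub + e@value * (inPlane + zTerm <= 1)
    }
    acc <- acc + sub
  }
  acc <- acc / supersample^3
  if (min(acc) < -1e-12)
    .validationError("composite phantom attenuation is negative somewhere")
  volume(acc, grid)
}

#' Simulate a helical scan of an analytic phantom
#'
#' Noiseless path: \code{forwardProject(rasterize(spec, grid), geometry)}.
#' Noisy path: per detector cell with line integral p, counts
#' \code{N ~ Poisson(i0 * exp(-p))} (plus Gaussian electronic noise when
#' sigma > 0), clamped at >= 1, log-transformed back to
#' \code{p_hat = log(i0 / N)}.  Seeded and reproducible; a warning is issued
#' when clamping affects more than 1 percent of cells (dose too low).
#'
#' @param spec a \code{PhantomSpec}.
#' @param geometry a \code{ScanGeometry}.
#' @param grid the rasterization grid.
#' @param noise a \code{\linkS4class{NoiseModel}} or NULL for noiseless data.
#' @param supersample passed to \code{\link{rasterize}}.
#' @return a \code{\linkS4class{Sinogram}}.
#' @export
simulateScan <- function(spec, geometry, grid, noise = NULL, supersample = 1L) {
  vol <- rasterize(spec, grid, supersample = supersample)
  sino <- forwardProject(vol, geometry)
  if (is.null(noise)) return(sino)
  p <- sino@data
  set.seed(noise@seed)
  expected <- noise@i0 * exp(-p)
  n <- stats::rpois(length(expected), lambda = as.vector(expected))
  if (noise@sigma > 0) n <- n + stats::rnorm(length(n), sd = noise@sigma)
  clamped <- n < 1
  if (mean(clamped) > 0.01)
    warning(sprintf("photon starvation: %.1f%% of cells clamped at 1 count",
                    100 * mean(clamped)))
  n <- pmax(n, 1)
  phat <- array(log(noise@i0 / n), dim = dim(p))
  sinogram(phat, geometry)
}

#' Uniform sparse-view subsampling
#'
#' Keeps views with index 0 mod \code{step} and rescales the geometry's
#' views-per-rotation (hence the angular and table steps) accordingly --
#' equivalent to rotating and translating \code{step} times faster.  The full
#' 2304-view protocol subsamples to 576 / 288 / 144 views per rotation at
#' steps 4 / 8 / 16.
#'
#' @param sino a \code{Sinogram}; @param step positive integer dividing
#'   views-per-rotation.
#' @export
subsampleViews <- function(sino, step) {
  step <- as.integer(step)
  if (step < 1L) .validationError("step must be >= 1")
  if (step == 1L) return(sino)
  g <- sino@geometry
  if (g@viewsPerRotation %% step != 0L)
    .validationError(sprintf("step %d does not divide views per rotation %d",
                             step, g@viewsPerRotation))
  keep <- seq(1L, g@nViews, by = step)
  g2 <- scanGeometry(g@sourceRadius, g@sourceToDetector, g@nRows, g@nChannels,
                     g@rowHeight, g@channelWidth,
                     g@viewsPerRotation %/% step, length(keep),
                     g@startAngle, g@pitch, g@zStart,
                     g@ffs[keep, , drop = FALSE])
  sinogram(sino@data[keep, , , drop = FALSE], g2)
}

#' Desk-scale scan preset
#'
#' A scaled-down replica of a 64-row, 2304-view-per-rotation clinical helical
#' protocol: 64 x 64 x 32 voxel grid (1 x 1 x 2 mm), 16 detector rows (2 mm at
#' the isocenter, matching the slice thickness) and 144 channels at 0.75 mm,
#' keeping the clinical convention that the in-plane detector pitch is finer
#' than the voxel pitch (otherwise high-frequency image modes are invisible to
#' the projector), 96 views per rotation at pitch 1, with enough rotations to
#' cover the grid in z.
#' @param rotations number of rotations (default 3).
#' @param viewsPerRotation views per rotation (default 96).
#' @return list with \code{grid} and \code{geometry}.
#' @export
deskPreset <- function(rotations = 3, viewsPerRotation = 96L) {
  grid <- volumeGrid(c(64L, 64L, 32L), spacing = c(1, 1, 2))
  sdd <- 1100; R <- 600
  geometry <- scanGeometry(
    sourceRadius = R, sourceToDetector = sdd,
    nRows = 16L, nChannels = 144L,
    rowHeight = 2 * sdd / R, channelWidth = 0.75 * sdd / R,
    viewsPerRotation = as.integer(viewsPerRotation),
    nViews = as.integer(round(rotations * viewsPerRotation)),
    pitch = 1)
  list(grid = grid, geometry = geometry)
}
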