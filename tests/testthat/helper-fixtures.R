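# Shared small fixtures, built in code at test time.

# tiny helical geometry: nViews views over one rotation unless told otherwise
tinyGeometry <- function(nViews = 24L, nRows = 4L, nChannels = 24L,
                         viewsPerRotation = nViews, pitch = 1,
                         rowHeightIso = 4, channelWidthIso = 3, ffs = NULL) {
  R <- 600; sdd <- 1100
  scanGeometry(R, sdd, nRows, nChannels,
               rowHeightIso * sdd / R, channelWidthIso * sdd / R,
               viewsPerRotation, nViews, pitch = pitch, ffs = ffs)
}

# random volume on an n-cube grid (spacing chosen so the FOV covers it)
randomVolume <- function(n = 16L, spacing = 2, seed = 1L) {
  set.seed(seed)
  volume(array(rnorm(prod(rep(n, 3))), dim = rep(n, 3)),
         volumeGrid(n, spacing = spacing))
}

randomSinogram <- function(geometry, seed = 1L) {
  set.seed(seed)
  d <- c(geometry@nViews, geometry@nRows, geometry@nChannels)
  sinogram(array(rnorm(prod(d)), dim = d), geometry)
}

relRmse <- function(vol, truth) {
  a <- if (is(vol, "Volume")) vol@data else vol
  b <- if (is(truth, "Volume")) truth@data else truth
  sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
}

coeffFlat <- function(coeffs) helicalTF:::.coeffFlatten(coeffs)

# dense matrix of the forward operator built by applying A to unit vectors;
# independent oracle for the tiny normal-equation tests
denseOperator <- function(grid, geometry) {
  nvox <- prod(grid@n)
  nray <- geometry@nViews * geometry@nRows * geometry@nChannels
  A <- matrix(0, nray, nvox)
  for (i in seq_len(nvox)) {
    e <- array(0, dim = grid@n)
    e[i] <- 1
    A[, i] <- as.vector(forwardProject(volume(e, grid), geometry)@data)
  }
  A
}
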