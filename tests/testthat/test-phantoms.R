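test_that("rasterization reproduces analytic volumes and is additive", {
  grid <- volumeGrid(48L, spacing = 1)
  expect_true(all(voxelData(rasterize(phantomSpec(), grid)) == 0))

  r <- 16
  sph <- phantomSpec(ellipsoid(c(0, 0, 0), rep(r, 3), 0, 1))
  v <- rasterize(sph, grid)
  volEst <- sum(voxelData(v)) * prod(grid@spacing)
  expect_equal(volEst, 4 / 3 * pi * r^3, tolerance = 0.02)

  e1 <- ellipsoid(c(-10, 0, 0), c(6, 5, 7), 0.3, 0.02)
  e2 <- ellipsoid(c(12, 4, 2), c(5, 6, 4), -0.2, 0.01)
  both <- voxelData(rasterize(phantomSpec(e1, e2), grid))
  sep <- voxelData(rasterize(phantomSpec(e1), grid)) +
    voxelData(rasterize(phantomSpec(e2), grid))
  expect_equal(both, sep, tolerance = 1e-14)

  # negative composite attenuation is rejected
  hole <- phantomSpec(ellipsoid(c(0, 0, 0), c(5, 5, 5), 0, -0.01))
  expect_error(rasterize(hole, grid), class = "helicalTF_validation_error")
})

test_that("noiseless simulation equals projecting the rasterized phantom", {
  g <- tinyGeometry()
  grid <- volumeGrid(16L, spacing = 3)
  spec <- twoEllipsoidPhantom(scale = 0.5)
  s1 <- simulateScan(spec, g, grid)
  s2 <- forwardProject(rasterize(spec, grid), g)
  expect_identical(sinoData(s1), sinoData(s2))
  expect_true(all(sinoData(simulateScan(phantomSpec(), g, grid)) == 0))
})

test_that("Poisson noise has the expected first-order statistics", {
  g <- tinyGeometry(nViews = 12L, nRows = 8L, nChannels = 110L)
  grid <- volumeGrid(16L, spacing = 3)
  # empty phantom: p = 0, so p_hat = log(I0 / N) should be centered near 0
  i0 <- 1e5
  s <- simulateScan(phantomSpec(), g, grid, noise = noiseModel(i0, seed = 3L))
  phat <- as.vector(sinoData(s))
  expect_gte(length(phat), 1e4)
  se <- sqrt(1 / i0 / length(phat))
  expect_lt(abs(mean(phat)), 3 * se)
  # delta-method variance: var(p_hat) ~ exp(p)/I0 = 1/I0 here, within 20%
  expect_equal(stats::var(phat), 1 / i0, tolerance = 0.2)

  # fixed seed reproduces the draw exactly
  s2 <- simulateScan(phantomSpec(), g, grid, noise = noiseModel(i0, seed = 3L))
  expect_identical(sinoData(s), sinoData(s2))

  # photon starvation warns
  thick <- phantomSpec(ellipsoid(c(0, 0, 0), c(20, 20, 20), 0, 0.5))
  expect_warning(simulateScan(thick, g, grid, noise = noiseModel(50, seed = 1L)),
                 "clamped")
})

test_that("sparse-view subsampling follows the clinical protocol arithmetic", {
  g <- tinyGeometry(nViews = 2304L, viewsPerRotation = 2304L, nRows = 1L,
                    nChannels = 2L)
  set.seed(8)
  s <- sinogram(array(rnorm(2304 * 2), dim = c(2304L, 1L, 2L)), g)
  for (step in c(4L, 8L, 16L)) {
    sub <- subsampleViews(s, step)
    expect_equal(scanGeometryOf(sub)@viewsPerRotation, 2304L %/% step)
    expect_equal(dim(sinoData(sub))[1], 2304L %/% step)
    # kept views are the 0 mod step originals
    expect_identical(sinoData(sub)[, 1, 1], sinoData(s)[seq(1, 2304, step), 1, 1])
  }
  expect_equal(scanGeometryOf(subsampleViews(s, 4L))@viewsPerRotation, 576L)
  expect_equal(scanGeometryOf(subsampleViews(s, 16L))@viewsPerRotation, 144L)

  # identity and composition
  expect_identical(sinoData(subsampleViews(s, 1L)), sinoData(s))
  ab <- subsampleViews(subsampleViews(s, 4L), 4L)
  expect_identical(sinoData(ab), sinoData(subsampleViews(s, 16L)))
  expect_equal(scanGeometryOf(ab)@viewsPerRotation, 144L)
  # angular + table steps rescale consistently (faster rotation equivalent)
  expect_equal(zPerView(scanGeometryOf(subsampleViews(s, 8L))),
               8 * zPerView(g))
  expect_error(subsampleViews(s, 5L), class = "helicalTF_validation_error")
})

test_that("phantom spec tables round-trip", {
  spec <- twoEllipsoidPhantom()
  path <- withr::local_tempfile(fileext = ".txt")
  writePhantomSpec(spec, path)
  spec2 <- readPhantomSpec(path)
  grid <- volumeGrid(24L, spacing = 2.5)
  expect_equal(voxelData(rasterize(spec2, grid)), voxelData(rasterize(spec, grid)))
})
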