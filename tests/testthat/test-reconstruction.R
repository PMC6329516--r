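# tiny shared problem: 8^3 grid, 12 views -- small enough for a dense oracle
tinyProblem <- function() {
  grid <- volumeGrid(8L, spacing = 5)
  geom <- tinyGeometry(nViews = 12L, nRows = 6L, nChannels = 36L,
                       rowHeightIso = 7, channelWidthIso = 1.8)
  spec <- phantomSpec(ellipsoid(c(0, 0, 0), c(14, 11, 16), 0, 0.02),
                      ellipsoid(c(4, -2, 2), c(6, 5, 7), 0.3, 0.01))
  list(grid = grid, geom = geom, spec = spec)
}

test_that("cg solves trivial and dense-verified systems", {
  # operator 2I: one step to the exact answer
  set.seed(31)
  b <- array(rnorm(4^3), dim = c(4L, 4L, 4L))
  sol <- cgSolve(function(x) 2 * x, b, maxIterations = 5L, tolerance = 1e-12)
  expect_equal(sol$x, b / 2, tolerance = 1e-12)
  expect_true(sol$converged)
  expect_lte(sol$iterations, 2L)

  # tiny helical system vs an explicit dense solve of the normal equations
  tp <- tinyProblem()
  A <- denseOperator(tp$grid, tp$geom)
  y <- as.vector(sinoData(simulateScan(tp$spec, tp$geom, tp$grid)))
  mu <- 0.5
  M <- crossprod(A) + mu * diag(ncol(A))
  xDense <- solve(M, crossprod(A, y))
  applyOp <- function(x) {
    array(voxelData(backProject(forwardProject(volume(x, tp$grid), tp$geom),
                                tp$grid)), dim = tp$grid@n) + mu * x
  }
  rhs <- array(voxelData(backProject(sinogram(array(y, dim = dim(sinoData(
    simulateScan(tp$spec, tp$geom, tp$grid)))), tp$geom), tp$grid)),
    dim = tp$grid@n)
  sol2 <- cgSolve(applyOp, rhs, maxIterations = 400L, tolerance = 1e-10)
  expect_lt(sqrt(sum((as.vector(sol2$x) - xDense)^2)) / sqrt(sum(xDense^2)),
            1e-6)

  # energy-norm error decreases monotonically (the CG convergence guarantee);
  # the 2-norm residual is allowed tiny upticks
  errs <- vapply(seq_len(30), function(k) {
    s <- cgSolve(applyOp, rhs, maxIterations = k, tolerance = 0)
    e <- as.vector(s$x) - xDense
    sqrt(sum(e * (M %*% e)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8 * errs[1]))

  expect_error(cgSolve(function(x) x, array(NA_real_, dim = c(2L, 2L, 2L))),
               class = "helicalTF_validation_error")
})

test_that("unregularized ADMM settles on the normal equations", {
  tp <- tinyProblem()
  sino <- simulateScan(tp$spec, tp$geom, tp$grid)
  cfg <- admmConfig(lambda = 0, mu = 0.1, levels = 1L,
                    outerIterations = 25L, cgIterations = 40L,
                    cgTolerance = 1e-10)
  rec <- admmReconstruct(sino, tp$grid, cfg)
  x <- voxelData(reconVolume(rec))
  # fixed point solves A^T A x = A^T y (checked against the dense oracle, on
  # the original data scale)
  A <- denseOperator(tp$grid, tp$geom)
  y <- as.vector(sinoData(sino))
  lhs <- crossprod(A) %*% as.vector(x)
  rhs <- crossprod(A, y)
  expect_lt(sqrt(sum((lhs - rhs)^2)) / sqrt(sum(rhs^2)), 1e-4)
  # fidelity collapses for consistent noiseless data
  expect_lt(sqrt(2 * utils::tail(fidelityTrace(rec), 1)) /
              sqrt(sum((y / max(abs(y)))^2)), 1e-4)
})

test_that("ADMM objective settles and runs are deterministic", {
  tp <- tinyProblem()
  sino <- simulateScan(tp$spec, tp$geom, tp$grid)
  cfg <- admmConfig(lambda = 5e-4, mu = 1, levels = 2L,
                    outerIterations = 15L, cgIterations = 10L)
  rec1 <- admmReconstruct(sino, tp$grid, cfg)
  rec2 <- admmReconstruct(sino, tp$grid, cfg)
  expect_identical(objectiveTrace(rec1), objectiveTrace(rec2))
  expect_identical(voxelData(reconVolume(rec1)), voxelData(reconVolume(rec2)))
  # non-increasing after burn-in, small relative upticks tolerated
  tr <- objectiveTrace(rec1)
  late <- tr[3:length(tr)]
  expect_true(all(diff(late) <= 1e-6 * abs(late[-length(late)]) + 1e-12))
})

test_that("TF reconstruction recovers a noiseless phantom on a small grid", {
  grid <- volumeGrid(c(32L, 32L, 16L), spacing = c(1.5, 1.5, 3))
  geom <- tinyGeometry(nViews = 144L, viewsPerRotation = 48L, nRows = 8L,
                       nChannels = 72L, rowHeightIso = 3,
                       channelWidthIso = 1.0)
  spec <- twoEllipsoidPhantom(scale = 0.9)
  truth <- rasterize(spec, grid)
  sino <- simulateScan(spec, geom, grid)
  rec <- admmReconstruct(sino, grid,
                         admmConfig(lambda = 1e-5, mu = 1, levels = 2L,
                                    outerIterations = 25L, cgIterations = 10L))
  expect_lt(relRmse(reconVolume(rec), truth), 0.03)

  # TV (single-level first-difference weights) behaves comparably
  tv <- tvReconstruct(sino, grid, lambda1 = 1e-5,
                      config = admmConfig(outerIterations = 25L,
                                          cgIterations = 10L))
  expect_lt(relRmse(reconVolume(tv), truth), 0.05)
})

test_that("TV strength flattens the reconstruction monotonically", {
  tp <- tinyProblem()
  sino <- simulateScan(tp$spec, tp$geom, tp$grid)
  tvNormOf <- function(v) {
    tfNorm(tfForward(voxelData(v), 1L), regWeights(matrix(c(1, 0), 1, 2)))
  }
  norms <- vapply(c(1e-5, 1e-4, 1e-3), function(lam) {
    r <- tvReconstruct(sino, tp$grid, lambda1 = lam,
                       config = admmConfig(outerIterations = 40L,
                                           cgIterations = 15L))
    tvNormOf(reconVolume(r))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("FDK reconstructs a uniform sphere value and is linear", {
  p <- deskPreset(rotations = 3, viewsPerRotation = 96L)
  spec <- phantomSpec(ellipsoid(c(0, 0, 0), c(20, 20, 20), 0, 0.02))
  sino <- simulateScan(spec, p$geometry, p$grid)
  rec <- fdkReconstruct(sino, p$grid)
  ctr <- voxelData(rec)[32:33, 32:33, 16:17]
  expect_equal(mean(ctr), 0.02, tolerance = 0.05)

  # zero data -> zero volume; linearity in the sinogram
  z <- fdkReconstruct(sinogram(array(0, dim = dim(sinoData(sino))),
                               p$geometry), p$grid)
  expect_true(all(voxelData(z) == 0))
  r2 <- fdkReconstruct(sinogram(2 * sinoData(sino), p$geometry), p$grid)
  expect_equal(voxelData(r2), 2 * voxelData(rec), tolerance = 1e-10)

  # insufficient z coverage is reported with the uncovered slices
  short <- scanGeometry(600, 1100, 4L, 96L, 2 * 1100 / 600, 0.75 * 1100 / 600,
                        96L, 48L, pitch = 1)
  sinoShort <- simulateScan(spec, short, p$grid)
  expect_error(fdkReconstruct(sinoShort, p$grid), "slice",
               class = "helicalTF_validation_error")
})
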