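test_that("refinement masks carry the tight-frame structure", {
  for (l in 1:3) {
    mb <- maskBank(l)
    expect_equal(sum(mb$w0), 1)        # averaging mask
    expect_equal(sum(mb$w1), 0)        # first difference annihilates constants
    expect_equal(sum(mb$w2), 0)        # second difference annihilates constants
    expect_equal(mb$dilation, 2L^(l - 1L))
    # per-level 1D tight-frame identity on random periodic signals
    set.seed(l)
    x <- array(rnorm(32), dim = c(32L, 1L, 1L))
    recon <- Reduce(`+`, lapply(list(mb$w0, mb$w1, mb$w2), function(w) {
      taps <- w[c(1L, mb$dilation + 1L, 2L * mb$dilation + 1L)]
      y <- helicalTF:::.axisFilter(x, taps, mb$dilation, 1L)
      helicalTF:::.axisFilter(y, taps, mb$dilation, 1L, adjoint = TRUE)
    }))
    expect_equal(max(abs(recon - x)), 0, tolerance = 1e-12)
  }
})

test_that("constant volumes land entirely in the lowpass", {
  x <- array(3.7, dim = c(12L, 10L, 8L))
  for (L in 1:2) {
    cf <- tfForward(x, L)
    for (l in seq_len(L)) for (j in 1:2) {
      b <- tfBand(cf, l, j)
      expect_true(all(abs(c(b$x, b$y, b$z)) < 1e-14))
    }
  }
  # uni-level lowpass (the j = 0 band) reproduces the constant: adjoint of
  # the lowpass triple alone gives back c
  cf1 <- tfForward(x, 1L)
  lp <- tfBand(cf1, band = "lowpass")
  expect_equal(lp$x, array(3.7 / sqrt(3), dim = dim(x)), tolerance = 1e-12)
  expect_equal(max(abs(tfAdjoint(cf1) - x)), 0, tolerance = 1e-12)
})

test_that("the first-difference band matches the stencil on a linear ramp", {
  n <- 16L
  x <- array(rep(seq_len(n) - 1, times = n * n), dim = c(n, n, n))
  cf <- tfForward(x, 1L)
  bx <- tfBand(cf, 1L, 1L)$x
  # interior voxels: (1/sqrt(3)) * (sqrt(2)/4) * (x_{i-1} - x_{i+1})
  expect_equal(bx[8, 5, 5], -(1 / sqrt(3)) * (sqrt(2) / 2), tolerance = 1e-12)
  expect_true(all(abs(bx[3:14, , ] + (1 / sqrt(3)) * (sqrt(2) / 2)) < 1e-12))
})

test_that("W^T W = I and Parseval hold on random anisotropic volumes", {
  set.seed(42)
  x <- array(rnorm(16 * 12 * 8), dim = c(16L, 12L, 8L))
  for (L in 1:3) {
    cf <- tfForward(x, L)
    expect_lt(max(abs(tfAdjoint(cf) - x)), 1e-10)
    # Parseval: ||Wx||_2 = ||x||_2
    expect_equal(sqrt(sum(coeffFlat(cf)^2)), sqrt(sum(x^2)),
                 tolerance = 1e-10)
  }
  expect_error(tfForward(x, 5L), class = "helicalTF_validation_error")
})

test_that("adjoint satisfies the dot-product identity", {
  set.seed(7)
  x <- array(rnorm(12^3), dim = c(12L, 12L, 12L))
  Wx <- tfForward(x, 2L)
  # random coefficient object with the same structure
  c2 <- tfForward(array(rnorm(12^3), dim = c(12L, 12L, 12L)), 2L)
  lhs <- sum(coeffFlat(Wx) * coeffFlat(c2))
  rhs <- sum(x * tfAdjoint(c2))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the weighted framelet norm matches hand-computed cases", {
  dims <- c(6L, 6L, 6L)
  cf <- helicalTF:::.coeffZero(dims, 1L)
  expect_equal(tfNorm(cf, regWeights(1, 1L)), 0)

  # single voxel with band value (3, 4, 0) -> magnitude 5
  b <- cf@bands[[1]]$B1
  b$x[2, 2, 2] <- 3; b$y[2, 2, 2] <- 4
  cf@bands[[1]]$B1 <- b
  expect_equal(tfNorm(cf, regWeights(matrix(c(1, 0), 1, 2))), 5)
  # homogeneity of degree 1
  cf2 <- helicalTF:::.coeffMap2(cf, cf, function(a, b) 3 * a)
  expect_equal(tfNorm(cf2, regWeights(matrix(c(1, 0), 1, 2))), 15)
})

test_that("TV weight pattern reproduces the isotropic TV norm up to 1/sqrt(6)", {
  set.seed(3)
  x <- array(rnorm(12 * 10 * 8), dim = c(12L, 10L, 8L))
  tfn <- tfNorm(tfForward(x, 1L), regWeights(matrix(c(1, 0), 1, 2)))
  # independent central-difference isotropic TV with periodic boundaries
  sh <- function(a, s, ax) helicalTF:::.axisTake(a, s, ax)
  g <- lapply(1:3, function(ax) (sh(x, -1, ax) - sh(x, 1, ax)) / 2)
  tv <- sum(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2))
  expect_equal(tfn, tv / sqrt(6), tolerance = 1e-10)
})

test_that("isotropic shrinkage matches its closed form and is non-expansive", {
  dims <- c(5L, 5L, 5L)
  cf <- helicalTF:::.coeffZero(dims, 1L)
  b <- cf@bands[[1]]$B1
  b$x[1, 1, 1] <- 3; b$y[1, 1, 1] <- 4      # magnitude 5
  b$x[2, 1, 1] <- 1; b$y[2, 1, 1] <- 2      # magnitude sqrt(5) < t
  cf@bands[[1]]$B1 <- b
  out <- tfShrink(cf, regWeights(matrix(c(2.5, 0), 1, 2)), mu = 1)
  ob <- tfBand(out, 1L, 1L)
  expect_equal(c(ob$x[1, 1, 1], ob$y[1, 1, 1], ob$z[1, 1, 1]), c(1.5, 2, 0))
  expect_equal(c(ob$x[2, 1, 1], ob$y[2, 1, 1]), c(0, 0))  # dead zone

  # zero threshold is the identity
  idn <- tfShrink(cf, regWeights(matrix(0, 1, 2)), mu = 1)
  expect_identical(coeffFlat(idn), coeffFlat(cf))
  expect_error(tfShrink(cf, regWeights(1, 1L), mu = 0),
               class = "helicalTF_validation_error")

  # non-expansiveness on random pairs
  set.seed(9)
  for (i in 1:5) {
    a <- tfForward(array(rnorm(6^3), dim = c(6L, 6L, 6L)), 1L)
    b2 <- tfForward(array(rnorm(6^3), dim = c(6L, 6L, 6L)), 1L)
    w <- regWeights(matrix(runif(2), 1, 2), lambda0 = runif(1))
    sa <- coeffFlat(tfShrink(a, w, mu = 0.8))
    sb <- coeffFlat(tfShrink(b2, w, mu = 0.8))
    expect_lte(sqrt(sum((sa - sb)^2)),
               sqrt(sum((coeffFlat(a) - coeffFlat(b2))^2)) + 1e-12)
  }
})

test_that("shrink-then-adjoint with zero thresholds restores the volume", {
  set.seed(5)
  x <- array(rnorm(10^3), dim = c(10L, 10L, 10L))
  w0 <- regWeights(matrix(0, 2, 2), lambda0 = 0)
  back <- tfAdjoint(tfShrink(tfForward(x, 2L), w0, mu = 1.5))
  expect_lt(max(abs(back - x)), 1e-10)
})

test_that("framelet coefficients round-trip through the container format", {
  set.seed(6)
  x <- array(rnorm(8^3), dim = c(8L, 8L, 8L))
  cf <- tfForward(x, 2L)
  path <- withr::local_tempfile(fileext = ".fct")
  writeFrameletCoeffs(cf, path)
  cf2 <- readFrameletCoeffs(path)
  expect_equal(cf2@levels, 2L)
  # float32 payload: round-trip to single precision
  expect_equal(coeffFlat(cf2), coeffFlat(cf), tolerance = 1e-6)
  expect_lt(max(abs(tfAdjoint(cf2) - x)), 1e-5)
})
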