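mkVol <- function(a) volume(a, volumeGrid(dim(a), spacing = 1))

test_that("UQI matches its closed form and hits 1 for identical ROIs", {
  set.seed(21)
  a <- array(runif(5 * 5, 0.5, 1.5), dim = c(5L, 5L, 1L))
  roi <- roiMask(array(TRUE, dim = dim(a)))
  va <- mkVol(a)
  expect_identical(uqi(va, va, roi), 1)

  # printed 5x5 pair checked against a direct evaluation of the formula
  b <- a + 0.3
  vb <- mkVol(b)
  m1 <- mean(a); m2 <- mean(b)
  s1 <- mean((a - m1)^2); s2 <- mean((b - m2)^2)
  cv <- mean((a - m1) * (b - m2))
  direct <- (4 * cv * m1 * m2) / ((s1 + s2) * (m1^2 + m2^2))
  expect_equal(uqi(va, vb, roi), direct, tolerance = 1e-14)
  expect_lt(uqi(va, vb, roi), 1)  # luminance term degrades under a shift

  # symmetry and joint scale invariance
  expect_equal(uqi(vb, va, roi), uqi(va, vb, roi), tolerance = 1e-14)
  expect_equal(uqi(mkVol(2 * a), mkVol(2 * b), roi), uqi(va, vb, roi),
               tolerance = 1e-12)

  # bounded by 1 in magnitude on random pairs (Cauchy-Schwarz)
  for (i in 1:10) {
    x <- array(rnorm(125, mean = 2), dim = c(5L, 5L, 5L))
    y <- array(rnorm(125, mean = 2), dim = c(5L, 5L, 5L))
    r <- roiMask(array(TRUE, dim = c(5L, 5L, 5L)))
    u <- uqi(mkVol(x), mkVol(y), r)
    expect_lte(abs(u), 1 + 1e-12)
  }

  const <- mkVol(array(1, dim = dim(a)))
  expect_error(uqi(const, const, roi), class = "helicalTF_undefined_metric")
})

test_that("SNR and CNR match hand-computable cases and invariances", {
  a <- array(0, dim = c(4L, 4L, 1L))
  a[1:2] <- c(1, 3)
  roi2 <- roiMask(array(c(TRUE, TRUE, rep(FALSE, 14)), dim = dim(a)))
  expect_equal(snr(mkVol(a), roi2), 2)  # mean 2, population sd 1
  expect_equal(snr(mkVol(5 * a), roi2), 2)  # scale invariant

  expect_error(snr(mkVol(array(5, dim = c(4L, 4L, 1L))),
                   roiMask(array(TRUE, dim = c(4L, 4L, 1L)))),
               class = "helicalTF_undefined_metric")

  b <- array(0, dim = c(4L, 4L, 1L))
  b[1:2] <- c(2, 4)   # mean 3, sd 1
  b[3:4] <- c(0, 2)   # mean 1, sd 1
  roiA <- roiMask(array(seq_len(16) %in% 1:2, dim = dim(b)))
  roiB <- roiMask(array(seq_len(16) %in% 3:4, dim = dim(b)))
  expect_equal(cnr(mkVol(b), roiA, roiB), 2 / sqrt(2))
  expect_equal(cnr(mkVol(b + 7), roiA, roiB), 2 / sqrt(2))  # shift invariant
  expect_equal(cnr(mkVol(b), roiA, roiA), 0)
})

test_that("disc ROIs resolve to in-bounds voxel sets", {
  a <- array(rnorm(16 * 16 * 4), dim = c(16L, 16L, 4L))
  idx <- helicalTF:::.roiIndices(roiDisc(2L, c(8, 8), 3), dim(a))
  expect_true(all(idx >= 1 & idx <= length(a)))
  expect_gt(length(idx), 20)
  expect_error(helicalTF:::.roiIndices(roiDisc(9L, c(8, 8), 3), dim(a)),
               class = "helicalTF_validation_error")
})

test_that("an ideal step edge gives a flat MTF normalized to 1", {
  n <- 64L
  a <- array(0, dim = c(n, n, 1L))
  a[33:n, , 1] <- 1
  vol <- mkVol(a)
  pr <- lineProfile(0L, c(8, 32), c(56, 32), nSamples = 49L)
  m <- mtfFromEdge(vol, pr)
  expect_equal(m$mtf[1], 1)
  expect_true(all(abs(m$mtf - 1) < 1e-10))
})

test_that("a Gaussian edge reproduces its analytic Fourier pair", {
  n <- 128L
  sigma <- 2  # samples
  a <- array(0, dim = c(n, n, 1L))
  esf <- stats::pnorm((seq_len(n) - 64.5) / sigma)
  for (i in seq_len(n)) a[i, , 1] <- esf[i]
  vol <- mkVol(a)
  pr <- lineProfile(0L, c(16, 64), c(112, 64), nSamples = 97L)
  m <- mtfFromEdge(vol, pr)
  analytic <- exp(-2 * pi^2 * sigma^2 * m$frequency^2)
  keep <- analytic >= 0.1
  expect_lt(max(abs(m$mtf[keep] - analytic[keep])), 0.02)
  expect_equal(m$mtf[1], 1)

  # broader blur gives a pointwise lower MTF
  prev <- NULL
  for (s in c(1.5, 2.5, 3.5)) {
    b <- array(0, dim = c(n, n, 1L))
    es <- stats::pnorm((seq_len(n) - 64.5) / s)
    for (i in seq_len(n)) b[i, , 1] <- es[i]
    mm <- mtfFromEdge(mkVol(b), pr)
    sel <- mm$frequency <= 0.25
    expect_true(all(diff(mm$mtf[sel]) <= 1e-9))  # monotone non-increasing
    if (!is.null(prev)) expect_true(all(mm$mtf[sel] <= prev[sel] + 1e-9))
    prev <- mm$mtf
  }
})

test_that("profiles without an edge are rejected", {
  a <- array(rnorm(64 * 64, sd = 0.01), dim = c(64L, 64L, 1L))
  pr <- lineProfile(0L, c(8, 32), c(56, 32), nSamples = 49L)
  expect_error(mtfFromEdge(mkVol(a), pr), "edge",
               class = "helicalTF_validation_error")
})

test_that("volume normalization scales the robust maximum to 1", {
  set.seed(2)
  a <- array(runif(10^3, 0, 0.02), dim = c(10L, 10L, 10L))
  v <- normalizeVolume(mkVol(a))
  expect_equal(stats::quantile(abs(voxelData(v)), 0.999, names = FALSE), 1)
})
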