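#' Disc region of interest
#'
#' @param slice 0-based z slice; @param center 0-based in-plane (x, y) voxel
#'   coordinates; @param radius voxels; @param label used in metric tables.
#' @export
roiDisc <- function(slice, center, radius, label = "roi") {
  new("ROISpec", type = "disc", mask = array(logical(0), dim = c(0L, 0L, 0L)),
      slice = as.integer(slice), center = as.numeric(center),
      radius = as.numeric(radius), label = label)
}

#' Mask region of interest
#' @param mask logical 3D array; @param label label.
#' @export
roiMask <- function(mask, label = "roi") {
  new("ROISpec", type = "mask", mask = mask, slice = 0L, center = c(0, 0),
      radius = 1, label = label)
}

# resolve an ROI to linear voxel indices for a given grid size
.roiIndices <- function(roi, dims) {
  if (roi@type == "mask") {
    if (!identical(dim(roi@mask), as.integer(dims)))
      .validationError("ROI mask dims do not match the volume")
    idx <- which(roi@mask)
  } else {
    if (roi@slice < 0L || roi@slice >= dims[3])
      .validationError("ROI slice out of bounds")
    ix <- seq_len(dims[1]) - 1
    iy <- seq_len(dims[2]) - 1
    inDisc <- outer((ix - roi@center[1])^2, (iy - roi@center[2])^2, `+`) <=
      roi@radius^2
    idx <- which(inDisc) + roi@slice * dims[1] * dims[2]
  }
  if (length(idx) == 0L) .validationError("empty ROI")
  idx
}

.popSd <- function(x) sqrt(mean((x - mean(x))^2))
.popCov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Universal Quality Index
#'
#' \deqn{UQI = \frac{4\,\mathrm{Cov}(\mu, \mu_{true})}{\sigma^2 + \sigma_{true}^2}
#'       \cdot \frac{\bar\mu\,\bar\mu_{true}}{\bar\mu^2 + \bar\mu_{true}^2}}
#' over the ROI voxels (population statistics).  Equals 1 exactly iff the two
#' ROIs are identical and non-constant; the general formula ranges over
#' [-1, 1] (anti-correlated inputs give negative values), with [0, 1] the
#' relevant range for reconstruction-vs-truth comparisons.
#'
#' @param recon,reference \code{\linkS4class{Volume}}s of identical shape.
#' @param roi an \code{\linkS4class{ROISpec}}.
#' @export
uqi <- function(recon, reference, roi) {
  if (!identical(dim(recon@data), dim(reference@data)))
    .validationError("volume shapes differ")
  idx <- .roiIndices(roi, dim(recon@data))
  a <- recon@data[idx]; b <- reference@data[idx]
  va <- .popCov(a, a); vb <- .popCov(b, b)
  ma <- mean(a); mb <- mean(b)
  if (va + vb == 0)
    .undefinedMetric("UQI undefined: both ROIs are constant")
  if (ma^2 + mb^2 == 0)
    .undefinedMetric("UQI undefined: both ROI means are zero")
  # product form: identical non-constant inputs give exactly 2 * 1/2 = 1
  (4 * .popCov(a, b) / (va + vb)) * ((ma * mb) / (ma^2 + mb^2))
}

#' Signal-to-noise ratio over an ROI
#'
#' Mean over population standard deviation of the ROI voxels.
#' @param vol a \code{Volume}; @param roi an \code{ROISpec}.
#' @export
snr <- function(vol, roi) {
  x <- vol@data[.roiIndices(roi, dim(vol@data))]
  s <- .popSd(x)
  if (s == 0) .undefinedMetric("SNR undefined: zero variance in ROI")
  mean(x) / s
}

#' Contrast-to-noise ratio between an ROI and an air ROI
#'
#' \deqn{CNR = |\bar\mu_{ROI} - \bar\mu_{air}| / \sqrt{\sigma_{ROI}^2 +
#' \sigma_{air}^2}} with population variances.
#' @param vol a \code{Volume}; @param roi,roiAir \code{ROISpec}s.
#' @export
cnr <- function(vol, roi, roiAir) {
  a <- vol@data[.roiIndices(roi, dim(vol@data))]
  b <- vol@data[.roiIndices(roiAir, dim(vol@data))]
  den <- sqrt(.popSd(a)^2 + .popSd(b)^2)
  if (den == 0) .undefinedMetric("CNR undefined: zero combined variance")
  abs(mean(a) - mean(b)) / den
}

#' Line profile for edge analysis
#' @param slice 0-based slice index; @param start,end 0-based in-plane (x, y)
#'   voxel coordinates; @param nSamples samples along the segment.
#' @export
lineProfile <- function(slice, start, end, nSamples = 64L) {
  new("LineProfile", slice = as.integer(slice), start = as.numeric(start),
      end = as.numeric(end), nSamples = as.integer(nSamples))
}

# bilinear sample of one z-slice at fractional (x, y) voxel coordinates
.sampleSlice <- function(slice, xs, ys) {
  nx <- nrow(slice); ny <- ncol(slice)
  x0 <- pmin(pmax(floor(xs), 0), nx - 2)
  y0 <- pmin(pmax(floor(ys), 0), ny - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- cbind(x0 + 1, y0 + 1)
  i10 <- cbind(x0 + 2, y0 + 1)
  i01 <- cbind(x0 + 1, y0 + 2)
  i11 <- cbind(x0 + 2, y0 + 2)
  (1 - fx) * (1 - fy) * slice[i00] + fx * (1 - fy) * slice[i10] +
    (1 - fx) * fy * slice[i01] + fx * fy * slice[i11]
}

#' Sample an edge spread function along a line profile
#'
#' @param vol a \code{Volume}; @param profile a \code{LineProfile}.
#' @param smooth apply a 3-tap moving average to the sampled ESF (for noisy
#'   data); off by default so that ideal edges are left untouched.
#' @return list with \code{esf} and the sample spacing \code{ds} (mm).
#' @export
edgeSpreadFunction <- function(vol, profile, smooth = FALSE) {
  dims <- dim(vol@data)
  if (profile@slice < 0L || profile@slice >= dims[3])
    .validationError("profile slice out of bounds")
  ok <- function(p) all(p >= 0) && p[1] <= dims[1] - 1 && p[2] <= dims[2] - 1
  if (!ok(profile@start) || !ok(profile@end))
    .validationError("profile endpoints out of bounds")
  n <- profile@nSamples
  t <- seq(0, 1, length.out = n)
  xs <- profile@start[1] + t * (profile@end[1] - profile@start[1])
  ys <- profile@start[2] + t * (profile@end[2] - profile@start[2])
  esf <- .sampleSlice(vol@data[, , profile@slice + 1L], xs, ys)
  if (smooth) {
    k <- stats::filter(esf, rep(1 / 3, 3), sides = 2)
    esf[2:(n - 1)] <- k[2:(n - 1)]
  }
  sp <- vol@grid@spacing[1:2]
  ds <- sqrt(sum(((profile@end - profile@start) * sp)^2)) / (n - 1)
  list(esf = esf, ds = ds)
}

#' MTF from an edge profile
#'
#' Samples the edge spread function along the profile, differentiates it
#' between adjacent samples (half-sample-offset differencing, so an ideal
#' discrete step yields a single-impulse line spread function and a flat
#' MTF), takes the discrete Fourier magnitude of the LSF and normalizes so
#' that MTF(0) = 1.  Frequencies are in cycles/mm from the profile sample
#' spacing; values are returned up to the Nyquist frequency.
#'
#' @param vol a \code{Volume}; @param profile a \code{LineProfile}.
#' @param smooth pre-smooth the ESF (see \code{\link{edgeSpreadFunction}}).
#' @return list with \code{frequency} (cycles/mm) and \code{mtf}.
#' @export
mtfFromEdge <- function(vol, profile, smooth = FALSE) {
  es <- edgeSpreadFunction(vol, profile, smooth = smooth)
  esf <- es$esf
  n <- length(esf)
  m <- max(3L, n %/% 10L)
  head <- esf[seq_len(m)]; tail <- esf[seq(n - m + 1, n)]
  tailNoise <- max(stats::sd(head), stats::sd(tail))
  step <- abs(mean(tail) - mean(head))
  if (step == 0 || (tailNoise > 0 && step <= 5 * tailNoise))
    .validationError("no detectable edge along the profile")
  lsf <- diff(esf)
  spec <- abs(stats::fft(lsf))
  if (spec[1] == 0)
    .validationError("edge has zero net step; MTF normalization undefined")
  mtf <- spec / spec[1]
  nl <- length(lsf)
  freq <- (seq_len(nl) - 1) / (nl * es$ds)
  keep <- seq_len(floor(nl / 2) + 1L)
  list(frequency = freq[keep], mtf = mtf[keep])
}

#' Normalize a volume so its robust maximum is 1
#'
#' Divides by the 99.9th percentile of the voxel values (ignoring sign), the
#' convention used before computing image-quality metrics on reconstructed
#' volumes.
#' @param vol a \code{Volume}.
#' @export
normalizeVolume <- function(vol) {
  s <- stats::quantile(abs(vol@data), 0.999, names = FALSE)
  if (s == 0) return(vol)
  volume(vol@data / s, vol@grid)
}
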