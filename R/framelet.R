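# Piecewise-linear tight-frame refinement masks.  omega0 averages, omega1 and
# omega2 are first- and second-difference operators; their autocorrelations sum
# to a delta, which is what makes the transform tight.
.tfMasks <- list(
  w0 = c(1, 2, 1) / 4,
  w1 = sqrt(2) / 4 * c(1, 0, -1),
  w2 = c(-1, 2, -1) / 4
)

#' Dilated refinement masks for one level
#'
#' Level-l masks insert \code{2^(l-1) - 1} zeros between the three base taps
#' (the a-trous construction), so each mask remains three effective taps at
#' offsets \code{-d, 0, +d} with \code{d = 2^(l-1)}.
#' @param level level index l >= 1.
#' @return list with the full zero-inserted coefficient sequences \code{w0},
#'   \code{w1}, \code{w2} and the tap offset \code{dilation}.
#' @export
maskBank <- function(level) {
  d <- 2L^(level - 1L)
  expand <- function(t3) {
    w <- numeric(2L * d + 1L)
    w[c(1L, d + 1L, 2L * d + 1L)] <- t3
    w
  }
  list(w0 = expand(.tfMasks$w0), w1 = expand(.tfMasks$w1),
       w2 = expand(.tfMasks$w2), dilation = d)
}

# extract a circularly shifted copy of `a` along one axis: result_i = a_{i-s}
.axisTake <- function(a, s, axis) {
  n <- dim(a)[axis]
  idx <- ((seq_len(n) - 1 - s) %% n) + 1L
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# periodic correlation with a 3-tap dilated mask along one axis:
#   forward:  y_i = t1 * x_{i-d} + t2 * x_i + t3 * x_{i+d}
#   adjoint:  z_i = t1 * y_{i+d} + t2 * y_i + t3 * y_{i-d}
.axisFilter <- function(a, taps, d, axis, adjoint = FALSE) {
  s <- if (adjoint) -d else d
  taps[1] * .axisTake(a, s, axis) + taps[2] * a + taps[3] * .axisTake(a, -s, axis)
}

.zeroTriple <- function(dims) {
  z <- array(0, dim = dims)
  list(x = z, y = z, z = z)
}

#' Multilevel tensor-framelet transform W
#'
#' Filters each axis unfolding of the volume independently with the dilated
#' piecewise-linear framelet masks: per level l the band-j (j = 1, 2) axis-a
#' component is \code{(1/sqrt(3)) * omega_j^l} applied along axis a to that
#' axis's level-(l-1) lowpass, and the per-axis lowpass chain is advanced with
#' \code{omega_0^l}.  Boundary handling is periodic, so \code{W^T W = I} holds
#' exactly (to rounding).  For L = 1 the lowpass triple is the uni-level
#' averaging (j = 0) band.
#'
#' @param vol a \code{\linkS4class{Volume}} or 3D array.
#' @param levels number of levels L; \code{2^(L-1)} must be smaller than the
#'   smallest grid dimension.
#' @return a \code{\linkS4class{FrameletCoeffs}}.
#' @export
tfForward <- function(vol, levels = 1L) {
  x <- if (is(vol, "Volume")) vol@data else vol
  levels <- as.integer(levels)
  if (levels < 1L) .validationError("levels must be >= 1")
  dims <- dim(x)
  if (2^(levels - 1) >= min(dims))
    .validationError(sprintf(
      "level count %d too large for grid %s (need 2^(L-1) < min dim)",
      levels, paste(dims, collapse = "x")))
  s3 <- 1 / sqrt(3)
  chain <- list(x = x, y = x, z = x)
  bands <- vector("list", levels)
  for (l in seq_len(levels)) {
    d <- 2L^(l - 1L)
    b1 <- list(); b2 <- list()
    for (a in 1:3) {
      nm <- c("x", "y", "z")[a]
      c0 <- chain[[nm]]
      b1[[nm]] <- s3 * .axisFilter(c0, .tfMasks$w1, d, a)
      b2[[nm]] <- s3 * .axisFilter(c0, .tfMasks$w2, d, a)
      chain[[nm]] <- .axisFilter(c0, .tfMasks$w0, d, a)
    }
    bands[[l]] <- list(B1 = b1, B2 = b2)
  }
  lowpass <- lapply(chain, function(c0) s3 * c0)
  new("FrameletCoeffs", dims = as.integer(dims), levels = levels,
      bands = bands, lowpass = lowpass)
}

#' Adjoint tensor-framelet transform W^T
#'
#' Exact numerical transpose of \code{\link{tfForward}} (transposed periodic
#' correlations, same 1/sqrt(3) scaling, reversed per-axis lowpass chain).
#' Because the frame is tight, \code{tfAdjoint(tfForward(x, L))} returns
#' \code{x} to rounding error for any L.
#'
#' @param coeffs a \code{\linkS4class{FrameletCoeffs}}.
#' @param grid optional \code{\linkS4class{VolumeGrid}} to wrap the result as
#'   a \code{Volume}; otherwise a plain array is returned.
#' @export
tfAdjoint <- function(coeffs, grid = NULL) {
  L <- coeffs@levels
  out <- array(0, dim = coeffs@dims)
  for (a in 1:3) {
    nm <- c("x", "y", "z")[a]
    t <- coeffs@lowpass[[nm]]
    for (l in rev(seq_len(L))) {
      d <- 2L^(l - 1L)
      t <- .axisFilter(t, .tfMasks$w0, d, a, adjoint = TRUE) +
        .axisFilter(coeffs@bands[[l]]$B1[[nm]], .tfMasks$w1, d, a, adjoint = TRUE) +
        .axisFilter(coeffs@bands[[l]]$B2[[nm]], .tfMasks$w2, d, a, adjoint = TRUE)
    }
    out <- out + t
  }
  out <- out / sqrt(3)
  if (is.null(grid)) out else volume(out, grid)
}

#' Regularization weights
#'
#' One non-negative weight per (level, band) plus a weight for the final
#' lowpass term (default 0: penalizing the lowpass l1 is unusual and disabled
#' unless requested).  A scalar \code{lambda} is broadcast to every (l, j)
#' band.
#'
#' @param lambda scalar, or L x 2 matrix of per-(level, band) weights.
#' @param levels L (used when \code{lambda} is scalar).
#' @param lambda0 weight on the final lowpass term.
#' @return a \code{\linkS4class{RegWeights}}.
#' @export
regWeights <- function(lambda, levels = 1L, lambda0 = 0) {
  if (is.matrix(lambda)) {
    lam <- lambda
  } else {
    if (length(lambda) == 2L) {
      lam <- matrix(rep(as.numeric(lambda), each = levels), levels, 2L)
    } else {
      lam <- matrix(as.numeric(lambda), levels, 2L)
    }
  }
  new("RegWeights", lambda = lam, lambda0 = as.numeric(lambda0))
}

#' Weighted isotropic tensor-framelet norm
#'
#' \deqn{\sum_{l,j} \lambda_{l,j} \sum_v \sqrt{c_x^2 + c_y^2 + c_z^2}
#'       + \lambda_{L,0} \sum_v |c^L|}
#' i.e. the per-voxel magnitude of the three axis components of each band,
#' summed over voxels and weighted per (level, band), plus a scalar l1 on the
#' lowpass triple.  Non-negative and absolutely homogeneous of degree 1.
#'
#' @param coeffs a \code{FrameletCoeffs}; @param weights a \code{RegWeights}.
#' @export
tfNorm <- function(coeffs, weights) {
  if (nrow(weights@lambda) != coeffs@levels)
    .validationError("weights levels do not match coefficients")
  tot <- 0
  for (l in seq_len(coeffs@levels)) {
    for (j in 1:2) {
      lam <- weights@lambda[l, j]
      if (lam == 0) next
      b <- coeffs@bands[[l]][[paste0("B", j)]]
      tot <- tot + lam * sum(sqrt(b$x^2 + b$y^2 + b$z^2))
    }
  }
  if (weights@lambda0 > 0) {
    lp <- coeffs@lowpass
    tot <- tot + weights@lambda0 * (sum(abs(lp$x)) + sum(abs(lp$y)) + sum(abs(lp$z)))
  }
  tot
}

#' Isotropic framelet shrinkage
#'
#' Per voxel and band (l, j), with threshold \code{t = lambda_{l,j}/mu} and
#' magnitude \code{m = sqrt(c_x^2 + c_y^2 + c_z^2)}, returns
#' \code{c * max(m - t, 0)/m} (0 where m = 0): joint soft-thresholding of the
#' three axis components that preserves direction.  The lowpass triple is
#' soft-thresholded scalar-wise with \code{lambda0/mu}.  This is the exact
#' minimizer of the ADMM d-subproblem.
#'
#' @param coeffs a \code{FrameletCoeffs}.
#' @param thresholds a \code{RegWeights} (the lambda values).
#' @param mu the ADMM penalty parameter, > 0.
#' @return shrunk \code{FrameletCoeffs}.
#' @export
tfShrink <- function(coeffs, thresholds, mu = 1) {
  if (mu <= 0) .validationError("mu must be > 0")
  if (nrow(thresholds@lambda) != coeffs@levels)
    .validationError("threshold levels do not match coefficients")
  bands <- coeffs@bands
  for (l in seq_len(coeffs@levels)) {
    for (j in 1:2) {
      t <- thresholds@lambda[l, j] / mu
      if (t == 0) next
      key <- paste0("B", j)
      b <- bands[[l]][[key]]
      m <- sqrt(b$x^2 + b$y^2 + b$z^2)
      f <- ifelse(m > t, (m - t) / m, 0)
      bands[[l]][[key]] <- list(x = b$x * f, y = b$y * f, z = b$z * f)
    }
  }
  lowpass <- coeffs@lowpass
  t0 <- thresholds@lambda0 / mu
  if (t0 > 0) {
    soft <- function(a) sign(a) * pmax(abs(a) - t0, 0)
    lowpass <- lapply(lowpass, soft)
  }
  new("FrameletCoeffs", dims = coeffs@dims, levels = coeffs@levels,
      bands = bands, lowpass = lowpass)
}

#' Band accessor
#'
#' @param coeffs a \code{FrameletCoeffs}.
#' @param level level l; @param band 1 or 2, or "lowpass".
#' @return list of the three axis-component arrays \code{x}, \code{y}, \code{z}.
#' @export
tfBand <- function(coeffs, level = 1L, band = 1L) {
  if (identical(band, "lowpass")) return(coeffs@lowpass)
  coeffs@bands[[level]][[paste0("B", band)]]
}

setMethod("show", "FrameletCoeffs", function(object) {
  cat(sprintf(
    "FrameletCoeffs: %d level(s) on a %s grid, %d sub-volumes (per-axis lowpass)\n",
    object@levels, paste(object@dims, collapse = " x "),
    6L * object@levels + 3L))
})

# elementwise combination of two coefficient objects (same structure)
.coeffMap2 <- function(a, b, f) {
  bands <- a@bands
  for (l in seq_len(a@levels)) {
    for (key in c("B1", "B2")) {
      bands[[l]][[key]] <- list(
        x = f(a@bands[[l]][[key]]$x, b@bands[[l]][[key]]$x),
        y = f(a@bands[[l]][[key]]$y, b@bands[[l]][[key]]$y),
        z = f(a@bands[[l]][[key]]$z, b@bands[[l]][[key]]$z))
    }
  }
  lowpass <- list(
    x = f(a@lowpass$x, b@lowpass$x),
    y = f(a@lowpass$y, b@lowpass$y),
    z = f(a@lowpass$z, b@lowpass$z))
  new("FrameletCoeffs", dims = a@dims, levels = a@levels, bands = bands,
      lowpass = lowpass)
}

.coeffAdd <- function(a, b) .coeffMap2(a, b, `+`)
.coeffSub <- function(a, b) .coeffMap2(a, b, `-`)

.coeffZero <- function(dims, levels) {
  z <- .zeroTriple(dims)
  new("FrameletCoeffs", dims = as.integer(dims), levels = as.integer(levels),
      bands = rep(list(list(B1 = z, B2 = z)), levels), lowpass = z)
}

# flat vector view (used by norm/inner-product style tests)
.coeffFlatten <- function(coeffs) {
  parts <- list()
  for (l in seq_len(coeffs@levels))
    for (key in c("B1", "B2"))
      parts <- c(parts, coeffs@bands[[l]][[key]][c("x", "y", "z")])
  parts <- c(parts, coeffs@lowpass[c("x", "y", "z")])
  unlist(parts, use.names = FALSE)
}
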