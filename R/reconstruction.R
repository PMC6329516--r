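#' ADMM solver configuration
#'
#' Defaults assume the sinogram is normalized so that \code{max|y| = 1}
#' (\code{\link{admmReconstruct}} does this internally): \code{mu = 1} and a
#' small broadcast \code{lambda} are then reasonable starting points.  No
#' published values exist for these parameters; the defaults are this
#' package's own.
#'
#' @param lambda scalar or L x 2 matrix of regularization weights.
#' @param mu augmented-Lagrangian penalty (> 0).
#' @param levels framelet levels L.
#' @param lambda0 weight on the lowpass term (default 0).
#' @param outerIterations outer ADMM iterations.
#' @param cgIterations,cgTolerance inner conjugate-gradient budget.
#' @param init "zero" or "fdk" warm start.
#' @param relTolerance early stop when the relative iterate change drops below
#'   this value; 0 (default) disables early stopping for reproducibility.
#' @param seed integer seed recorded in manifests.
#' @return an \code{\linkS4class{ADMMConfig}}.
#' @export
admmConfig <- function(lambda = 1e-3, mu = 1, levels = 1L, lambda0 = 0,
                       outerIterations = 30L, cgIterations = 20L,
                       cgTolerance = 1e-6, init = "zero", relTolerance = 0,
                       seed = 1L) {
  w <- if (is(lambda, "RegWeights")) lambda else
    regWeights(lambda, levels = levels, lambda0 = lambda0)
  new("ADMMConfig", weights = w, mu = as.numeric(mu),
      levels = as.integer(levels), outerIterations = as.integer(outerIterations),
      cgIterations = as.integer(cgIterations),
      cgTolerance = as.numeric(cgTolerance), init = init,
      relTolerance = as.numeric(relTolerance), seed = as.integer(seed))
}

#' Conjugate gradients for the regularized normal equations
#'
#' Solves \code{applyOp(x) = rhs} for a symmetric positive-definite linear
#' map (here \code{A^T A + mu I}) on volume arrays.  Stops when the relative
#' residual \code{||rhs - applyOp(x)|| / ||rhs||} falls below
#' \code{tolerance} or the iteration budget is exhausted.
#'
#' @param applyOp function taking and returning a 3D array.
#' @param rhs right-hand-side 3D array.
#' @param x0 optional warm-start array (default zeros).
#' @param maxIterations,tolerance budget.
#' @return list with \code{x}, \code{iterations}, \code{converged} and the
#'   per-iteration \code{residuals} (relative).
#' @export
cgSolve <- function(applyOp, rhs, x0 = NULL, maxIterations = 20L,
                    tolerance = 1e-6) {
  if (any(!is.finite(rhs))) .validationError("non-finite right-hand side")
  bnorm <- sqrt(sum(rhs^2))
  if (bnorm == 0)
    return(list(x = array(0, dim = dim(rhs)), iterations = 0L,
                converged = TRUE, residuals = numeric(0)))
  x <- if (is.null(x0)) array(0, dim = dim(rhs)) else x0
  r <- rhs - applyOp(x)
  p <- r
  rs <- sum(r^2)
  residuals <- numeric(0)
  iter <- 0L
  while (iter < maxIterations) {
    iter <- iter + 1L
    Ap <- applyOp(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rsNew <- sum(r^2)
    residuals[iter] <- sqrt(rsNew) / bnorm
    if (residuals[iter] <= tolerance) break
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  list(x = x, iterations = iter,
       converged = length(residuals) > 0 && utils::tail(residuals, 1) <= tolerance,
       residuals = residuals)
}

#' Tensor-framelet regularized reconstruction by ADMM (split Bregman)
#'
#' Minimizes \code{0.5 ||Ax - y||^2 + ||Wx||_{1,lambda}} by operator
#' splitting with auxiliaries d (shrinkage target) and v (scaled multiplier):
#' \enumerate{
#'   \item x-update: since \code{W^T W = I} the subproblem reduces to
#'     \code{(A^T A + mu I) x = A^T y + mu W^T(d - v)}, solved by warm-started
#'     conjugate gradients;
#'   \item d-update: isotropic framelet shrinkage of \code{Wx + v};
#'   \item multiplier update: \code{v <- v + Wx - d}.
#' }
#' The sinogram is scaled internally so \code{max|y| = 1} (traces are reported
#' on that scale); the returned volume is rescaled to the input units.
#'
#' @param sino a \code{\linkS4class{Sinogram}}.
#' @param grid the reconstruction \code{\linkS4class{VolumeGrid}}.
#' @param config an \code{\linkS4class{ADMMConfig}}.
#' @param verbose log one line per outer iteration to stderr.
#' @return a \code{\linkS4class{ReconResult}}.
#' @export
admmReconstruct <- function(sino, grid, config = admmConfig(),
                            verbose = FALSE) {
  validObject(config)
  y <- sino@data
  scale <- max(abs(y))
  if (scale == 0) scale <- 1
  ys <- sinogram(y / scale, sino@geometry)

  L <- config@levels
  mu <- config@mu
  lam <- config@weights
  geom <- sino@geometry

  Aty <- backProject(ys, grid)@data
  applyOp <- function(x) {
    backProject(forwardProject(volume(x, grid), geom), grid)@data + mu * x
  }

  x <- if (config@init == "fdk") fdkReconstruct(ys, grid)@data else
    array(0, dim = grid@n)
  d <- tfForward(x, L)
  v <- .coeffZero(grid@n, L)

  obj <- numeric(config@outerIterations)
  fid <- numeric(config@outerIterations)
  xPrev <- x
  nIter <- 0L
  for (it in seq_len(config@outerIterations)) {
    rhs <- Aty + mu * tfAdjoint(.coeffSub(d, v))
    sol <- cgSolve(applyOp, rhs, x0 = x,
                   maxIterations = config@cgIterations,
                   tolerance = config@cgTolerance)
    x <- sol$x
    if (any(!is.finite(x)))
      .solverError(sprintf("non-finite iterate at outer iteration %d", it))
    Wx <- tfForward(x, L)
    d <- tfShrink(.coeffAdd(Wx, v), lam, mu)
    v <- .coeffAdd(v, .coeffSub(Wx, d))

    res <- forwardProject(volume(x, grid), geom)@data - ys@data
    fid[it] <- 0.5 * sum(res^2)
    obj[it] <- fid[it] + tfNorm(Wx, lam)
    nIter <- it
    if (verbose)
      message(sprintf("admm iter %3d  fidelity %.6e  objective %.6e",
                      it, fid[it], obj[it]))
    if (config@relTolerance > 0) {
      dx <- sqrt(sum((x - xPrev)^2)) / max(sqrt(sum(x^2)), .Machine$double.eps)
      if (dx < config@relTolerance) break
    }
    xPrev <- x
  }
  new("ReconResult", volume = volume(x * scale, grid),
      objectiveTrace = obj[seq_len(nIter)], fidelityTrace = fid[seq_len(nIter)],
      iterationsRun = nIter)
}

#' Total-variation reconstruction as a framelet weight configuration
#'
#' With a single level and weights (lambda0 = 0, lambda1 > 0, lambda2 = 0) the
#' weighted framelet norm equals the isotropic finite-difference TV norm up to
#' a fixed constant (1/sqrt(6) relative to the central-difference TV), so TV
#' reconstruction is \code{\link{admmReconstruct}} with that weight pattern.
#'
#' @param sino,grid as \code{\link{admmReconstruct}}.
#' @param lambda1 weight on the first-difference band.
#' @param config optional \code{ADMMConfig} whose weights are overridden with
#'   the TV pattern (levels forced to 1).
#' @param verbose log per-iteration progress.
#' @export
tvReconstruct <- function(sino, grid, lambda1 = 1e-3, config = NULL,
                          verbose = FALSE) {
  if (is.null(config)) config <- admmConfig()
  w <- regWeights(matrix(c(lambda1, 0), 1L, 2L), lambda0 = 0)
  cfg <- new("ADMMConfig", weights = w, mu = config@mu, levels = 1L,
             outerIterations = config@outerIterations,
             cgIterations = config@cgIterations,
             cgTolerance = config@cgTolerance, init = config@init,
             relTolerance = config@relTolerance, seed = config@seed)
  admmReconstruct(sino, grid, cfg, verbose = verbose)
}

#' Simplified helical FDK reconstruction
#'
#' Approximate analytic baseline: cosine weighting, row-wise frequency-domain
#' ramp filtering with a Hann rolloff, and distance-weighted voxel-driven
#' backprojection over the views whose detector window covers each voxel,
#' with per-voxel angular redundancy normalization.  No Parker/Tam weighting
#' is applied and flying-focal-spot offsets are ignored (the filter assumes a
#' regular detector grid); the baseline aims to be a credible FDK, not a
#' vendor implementation.
#'
#' @param sino a \code{\linkS4class{Sinogram}} covering at least one rotation.
#' @param grid the reconstruction \code{\linkS4class{VolumeGrid}}.
#' @return a \code{\linkS4class{Volume}}.
#' @export
fdkReconstruct <- function(sino, grid) {
  g <- sino@geometry
  R <- g@sourceRadius
  magIso <- R / g@sourceToDetector
  chIso <- g@channelWidth * magIso
  rowIso <- g@rowHeight * magIso
  nV <- g@nViews; nR <- g@nRows; nC <- g@nChannels

  uIso <- (seq_len(nC) - 1 - (nC - 1) / 2) * chIso
  vIso <- (seq_len(nR) - 1 - (nR - 1) / 2) * rowIso
  # cosine weight on the virtual detector through the isocenter
  cw <- R / sqrt(R^2 + outer(vIso^2, uIso^2, `+`))  # nR x nC

  p <- sino@data
  for (v in seq_len(nV)) p[v, , ] <- p[v, , ] * cw

  # frequency-domain ramp (|f| in cycles/mm) with Hann rolloff, zero-padded
  np <- 2L * 2L^ceiling(log2(nC))
  f <- c(seq(0, np / 2), seq(np / 2 - 1, 1)) / (np * chIso)
  H <- f * (0.5 + 0.5 * cos(pi * f / max(f)))
  m <- matrix(0, np, nV * nR)
  m[seq_len(nC), ] <- matrix(aperm(p, c(3, 1, 2)), nrow = nC)
  m <- Re(stats::mvfft(stats::mvfft(m) * H, inverse = TRUE)) / np
  q <- aperm(array(m[seq_len(nC), ], dim = c(nC, nV, nR)), c(2, 3, 1))

  pm <- .poseMatrices(g)
  # nominal source (ffs ignored for the analytic baseline)
  v0 <- seq_len(nV) - 1
  theta <- g@startAngle + v0 * angularStep(g)
  srcNom <- cbind(R * cos(theta), R * sin(theta), g@zStart + v0 * zPerView(g))
  bp <- .cppFdkBackProject(as.vector(q), grid@n, grid@spacing, .lowCorner(grid),
                           srcNom, pm$ehat, pm$eu, pm$ev, nR, nC, rowIso, chIso,
                           R)
  cnt <- bp$count
  sliceCov <- apply(cnt > 0, 3, any)
  if (!all(sliceCov))
    .validationError(sprintf(
      "insufficient z-coverage: no views cover slice(s) %s",
      paste(which(!sliceCov) - 1, collapse = ", ")))
  out <- bp$sum
  out[cnt > 0] <- out[cnt > 0] * pi / cnt[cnt > 0]
  volume(out, grid)
}
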