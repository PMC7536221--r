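# Monomial exponents for total degree <= 3 in fixed order: increasing total
# degree, lexicographic (a, b, c) within a degree.  20 terms.
.poly3Exponents <- function() {
  ex <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  ex <- ex[ex$a + ex$b + ex$c <= 3L, ]
  ex <- ex[order(ex$a + ex$b + ex$c, ex$a, ex$b, ex$c), ]
  as.matrix(ex)
}

.poly3Design <- function(points, center, scale) {
  x <- (points[, 1] - center[1]) / scale
  y <- (points[, 2] - center[2]) / scale
  z <- (points[, 3] - center[3]) / scale
  ex <- .poly3Exponents()
  X <- matrix(1, nrow(points), nrow(ex))
  for (j in seq_len(nrow(ex)))
    X[, j] <- x^ex[j, 1] * y^ex[j, 2] * z^ex[j, 3]
  X
}

#' Fit a third-order spatial polynomial
#'
#' Weighted least-squares fit of a scalar field over world coordinates with
#' the 20-term monomial basis of total degree <= 3.  Coordinates are
#' centered on the (weighted) sample centroid and scaled by their radius of
#' gyration before fitting, for conditioning.  Noiseless samples of any
#' degree-<=3 polynomial are recovered exactly.
#'
#' @param points n x 3 matrix of world sample positions, mm (n >= 20).
#' @param values numeric(n) sampled field values.
#' @param weights optional non-negative weights.
#' @return a [Poly3Field-class].
#' @seealso [evalPoly3()]
#' @export
fitPoly3 <- function(points, values, weights = NULL) {
  points <- .asPointMatrix(points)
  n <- nrow(points)
  if (n < 20L)
    stop("polynomial fit failure: need at least 20 points, got ", n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be non-negative")
  wsum <- sum(weights)
  if (wsum <= 0) stop("polynomial fit failure: all weights are zero")
  center <- colSums(points * weights) / wsum
  rg <- sqrt(sum(weights * rowSums(sweep(points, 2L, center)^2)) / wsum)
  scale <- if (rg > 0) rg else 1
  X <- .poly3Design(points, center, scale)
  sw <- sqrt(weights)
  qrX <- qr(X * sw)
  if (qrX$rank < 20L)
    stop("polynomial fit failure: rank-deficient design (rank ",
         qrX$rank, " < 20); samples are not well spread in 3D")
  coef <- qr.coef(qrX, values * sw)
  new("Poly3Field", coefficients = as.numeric(coef), center = center,
      scale = scale)
}

#' Evaluate a third-order polynomial field
#'
#' @param poly a [Poly3Field-class].
#' @param points numeric(3) or n x 3 matrix of world points, mm.
#' @return field value(s).
#' @export
evalPoly3 <- function(poly, points) {
  points <- .asPointMatrix(points)
  as.numeric(.poly3Design(points, poly@center, poly@scale) %*%
               poly@coefficients)
}

#' Construct a volume mask
#' @param values logical 3D array.
#' @param grid the [VoxelGrid-class] it lives on.
#' @return a [VolumeMask-class].
#' @export
volumeMask <- function(values, grid) {
  storage.mode(values) <- "logical"
  new("VolumeMask", values = values, grid = grid)
}

# TRUE for frame pixels whose world center falls in a TRUE mask voxel
# (nearest-neighbour lookup).
.maskAtPoints <- function(mask, points) {
  idx <- round(indexCoords(mask@grid, points))
  s <- mask@grid@shape
  ok <- idx[, 1] >= 0 & idx[, 1] < s[1] &
        idx[, 2] >= 0 & idx[, 2] < s[2] &
        idx[, 3] >= 0 & idx[, 3] < s[3]
  out <- logical(nrow(points))
  lin <- 1 + idx[ok, 1] + s[1] * (idx[ok, 2] + s[2] * idx[ok, 3])
  out[ok] <- mask@values[lin]
  out
}

#' Background phase correction of a stack
#'
#' Estimates the smoothly varying background phase offset of one stack by
#' fitting a single third-order polynomial over world coordinates to the
#' phase values of all frames jointly, restricted to a fitting mask that
#' must exclude regions of true flow phase (heart and vessels).  The fitted
#' polynomial is then subtracted from every frame of the stack and the
#' result re-wrapped.  Geometry, sensitivities, transforms and weights are
#' untouched.
#'
#' @param stack a [FrameStack-class] or list of [FrameSample-class].
#' @param fitMask a [VolumeMask-class] selecting background voxels.
#' @param maxFitPoints fit at most this many mask pixels (uniform
#'   subsample) to bound the least-squares cost on large stacks.
#' @return the corrected stack, same class as the input; the fitted
#'   [Poly3Field-class] is attached as attribute \code{"poly"}.
#' @export
backgroundCorrectStack <- function(stack, fitMask, maxFitPoints = 50000L) {
  frs <- if (is(stack, "FrameStack")) stack@frames else stack
  pts <- vector("list", length(frs))
  val <- vector("list", length(frs))
  centers <- vector("list", length(frs))
  for (k in seq_along(frs)) {
    fr <- frs[[k]]
    s <- fr@grid2d@shape
    pix <- cbind(rep.int(seq_len(s[1]) - 1L, s[2]),
                 rep(seq_len(s[2]) - 1L, each = s[1]), 0)
    p <- applyTransform(fr@transform, worldCoords(fr@grid2d, pix))
    centers[[k]] <- p
    inMask <- .maskAtPoints(fitMask, p)
    pts[[k]] <- p[inMask, , drop = FALSE]
    val[[k]] <- as.numeric(fr@phase)[inMask]
  }
  P <- do.call(rbind, pts)
  v <- unlist(val)
  if (nrow(P) == 0L)
    stop("background correction: fitting mask selects no stack voxels")
  if (nrow(P) > maxFitPoints) {
    keep <- round(seq(1L, nrow(P), length.out = maxFitPoints))
    P <- P[keep, , drop = FALSE]
    v <- v[keep]
  }
  poly <- fitPoly3(P, v)
  for (k in seq_along(frs)) {
    bg <- evalPoly3(poly, centers[[k]])
    frs[[k]]@phase <- matrix(wrapPhase(as.numeric(frs[[k]]@phase) - bg),
                             nrow(frs[[k]]@phase), ncol(frs[[k]]@phase))
  }
  out <- if (is(stack, "FrameStack")) {
    stack@frames <- frs
    stack
  } else frs
  attr(out, "poly") <- poly
  out
}

#' Non-blood-pool mask from a magnitude cine volume
#'
#' A voxel is non-blood if and only if its magnitude stays below the
#' threshold in \emph{every} cardiac frame; any voxel bright in at least one
#' frame (blood passing through) is excluded.  The threshold is
#' \code{thresholdFraction} of the 99th-percentile magnitude.
#'
#' @param x a [CineMagnitudeVolume-class].
#' @param thresholdFraction fraction in (0, 1) of the robust (99th
#'   percentile) intensity.
#' @return a [VolumeMask-class] of non-blood voxels.
#' @export
nonbloodMask <- function(x, thresholdFraction = 0.5) {
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie strictly between 0 and 1")
  q99 <- stats::quantile(x@values, 0.99, names = FALSE)
  thr <- thresholdFraction * q99
  mx <- apply(x@values, 1:3, max)
  volumeMask(mx <= thr, x@grid)
}

#' Velocity drift correction
#'
#' Removes residual spatially smooth velocity offsets from a reconstructed
#' cine velocity volume.  Per Cartesian component: the per-voxel median over
#' cardiac frames is taken within the non-blood mask, a third-order spatial
#' polynomial is fitted to those medians over the mask voxels, and the
#' evaluated polynomial is subtracted from \emph{every} frame of that
#' component over the whole volume (global subtraction, not restricted to
#' the mask).
#'
#' @param v a [CineVelocityVolume-class].
#' @param mask a non-empty [VolumeMask-class] of non-blood voxels on the
#'   same grid.
#' @param maxFitPoints subsample bound for the polynomial fit.
#' @return the drift-corrected [CineVelocityVolume-class]; the three fitted
#'   [Poly3Field-class] objects are attached as attribute \code{"polys"}.
#' @export
velocityDriftCorrect <- function(v, mask, maxFitPoints = 50000L) {
  if (!any(mask@values)) stop("drift correction: mask is empty")
  if (!isTRUE(all.equal(mask@grid@affine, v@grid@affine)) ||
      !all(mask@grid@shape == v@grid@shape))
    stop("mask and velocity volume must share a grid")
  centers <- voxelCenters(v@grid)
  sel <- which(as.logical(mask@values))
  if (length(sel) > maxFitPoints)
    sel <- sel[round(seq(1L, length(sel), length.out = maxFitPoints))]
  P <- centers[sel, , drop = FALSE]
  nh <- dim(v@values)[4]
  nvox <- prod(v@grid@shape)
  polys <- vector("list", 3L)
  out <- v@values
  for (q in 1:3) {
    comp <- matrix(v@values[, , , , q], nvox, nh)
    med <- if (nh == 1L) comp[sel, 1] else
      apply(comp[sel, , drop = FALSE], 1L, stats::median)
    polys[[q]] <- fitPoly3(P, med)
    drift <- evalPoly3(polys[[q]], centers)
    # recycle over cardiac frames ((x, y, z) vary fastest, then h)
    out[, , , , q] <- out[, , , , q] - rep(drift, nh)
  }
  res <- new("CineVelocityVolume", values = out, grid = v@grid,
             phases = v@phases)
  attr(res, "polys") <- polys
  res
}
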