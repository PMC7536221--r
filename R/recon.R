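#' Edge-preserving spatial regularizer
#'
#' Charbonnier penalty on first differences of each velocity component over
#' the 6-neighborhood, per cine frame:
#' Reg(V) = sum over components, frames and neighbor pairs of
#' rho((v_i - v_i') / delta), with rho(t) = 2 (sqrt(1 + t^2) - 1).
#' Approximately quadratic for differences below delta (noise smoothing)
#' and linear above (edges between vessel and background are preserved).
#' The value is 0 iff every component is spatially constant within each
#' frame; the gradient is analytic.
#'
#' @param varr velocity array of dim (nx, ny, nz, nPhases, 3), or a
#'   [CineVelocityVolume-class].
#' @param delta edge-preservation scale, cm/s.
#' @param gradient if FALSE, skip the gradient (faster for line searches).
#' @return list with \code{value} and (if requested) \code{gradient}, an
#'   array matching \code{varr}.
#' @export
velocityRegularizer <- function(varr, delta = 5, gradient = TRUE) {
  if (is(varr, "CineVelocityVolume")) varr <- varr@values
  d <- dim(varr)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  value <- 0
  grad <- if (gradient) array(0, dim = d) else NULL
  rho <- function(t) 2 * (sqrt(1 + t^2) - 1)
  drho <- function(t) 2 * t / sqrt(1 + t^2)
  for (q in seq_len(d[5])) for (h in seq_len(d[4])) {
    a <- varr[, , , h, q]
    dim(a) <- d[1:3]
    g <- if (gradient) array(0, dim = d[1:3]) else NULL
    if (n1 > 1) {
      t1 <- (a[-n1, , , drop = FALSE] - a[-1, , , drop = FALSE]) / delta
      value <- value + sum(rho(t1))
      if (gradient) {
        dd <- drho(t1) / delta
        g[-n1, , ] <- g[-n1, , , drop = FALSE] + dd
        g[-1, , ] <- g[-1, , , drop = FALSE] - dd
      }
    }
    if (n2 > 1) {
      t2 <- (a[, -n2, , drop = FALSE] - a[, -1, , drop = FALSE]) / delta
      value <- value + sum(rho(t2))
      if (gradient) {
        dd <- drho(t2) / delta
        g[, -n2, ] <- g[, -n2, , drop = FALSE] + dd
        g[, -1, ] <- g[, -1, , drop = FALSE] - dd
      }
    }
    if (n3 > 1) {
      t3 <- (a[, , -n3, drop = FALSE] - a[, , -1, drop = FALSE]) / delta
      value <- value + sum(rho(t3))
      if (gradient) {
        dd <- drho(t3) / delta
        g[, , -n3] <- g[, , -n3, drop = FALSE] + dd
        g[, , -1] <- g[, , -1, drop = FALSE] - dd
      }
    }
    if (gradient) grad[, , , h, q] <- g
  }
  if (gradient) list(value = value, gradient = grad)
  else list(value = value)
}

# Vectorized eigenvalues of many symmetric 3x3 matrices given their unique
# entries; returns a matrix with columns (largest, middle, smallest).
.sym3Eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  cbind(e1, e2, e3)
}

.coverageFromSystem <- function(sys, config) {
  w <- sys$p
  m <- vector("list", 6L)
  idx <- 1L
  for (q1 in 1:3) for (q2 in q1:3) {
    m[[idx]] <- as.numeric(
      Matrix::crossprod(sys$W, w * sys$sdir[, q1] * sys$sdir[, q2]))
    idx <- idx + 1L
  }
  ev <- .sym3Eigenvalues(m[[1]], m[[4]], m[[6]], m[[2]], m[[3]], m[[5]])
  scale <- pmax(ev[, 1], 0)
  tol <- pmax(scale * 1e-6, max(scale) * 1e-12)
  rank <- (ev[, 1] > tol) + (ev[, 2] > tol) + (ev[, 3] > tol)
  condition <- ifelse(ev[, 3] > 0, ev[, 1] / ev[, 3], Inf)
  sampled <- scale > 0
  flagged <- !sampled | rank < config@minEncodingRank |
    condition > config@conditionLimit
  s <- sys$shape
  list(rank = array(as.integer(rank), s),
       condition = array(condition, s),
       sampled = array(sampled, s),
       flagged = array(flagged, s))
}

#' Per-voxel encoding coverage map
#'
#' For each target voxel, accumulates the weighted outer products of the
#' world-frame sensitivity directions of all samples touching it and
#' reports the rank and condition number of that 3x3 encoding matrix.
#' Voxels sampled by fewer than three non-colinear encoding directions
#' (rank < 3), with condition number above the limit, or not sampled at
#' all, are flagged unreliable: the inversion from phase projections to a
#' full velocity vector is under-determined there.
#'
#' @param frames frames with world-tagged sensitivities.
#' @param target the reconstruction [VoxelGrid-class].
#' @param model a [WeightModel-class].
#' @param config a [ReconConfig-class] (rank/condition flag limits).
#' @param phases cine phases (coverage pools all phases).
#' @return list of arrays: integer \code{rank}, numeric \code{condition},
#'   logical \code{sampled} and \code{flagged}.
#' @export
coverageMap <- function(frames, target, model = weightModel(),
                        config = reconConfig(), phases = 0) {
  sys <- .buildSystem(frames, target, model, phases)
  .coverageFromSystem(sys, config)
}

#' Reconstruct a cine velocity volume from multi-stack phase frames
#'
#' Solves the regularized inverse problem
#' argmin_V sum_k p_k || phi_k - phi_hat_k(V) ||^2 + lambda Reg(V)
#' over the three Cartesian velocity components per voxel per cine phase,
#' where the predicted phases are the PSF- and temporally-weighted
#' projections of V onto each frame's motion-corrected sensitivity
#' direction (see [predictPhase()]) and Reg is the edge-preserving
#' Charbonnier penalty of [velocityRegularizer()].
#'
#' V is initialized to zero and minimized by Polak-Ribiere nonlinear
#' conjugate gradient with Armijo backtracking (restart every 10
#' iterations); the objective is non-increasing across accepted iterations
#' and the solve is deterministic given its inputs.
#'
#' @param frames a [FrameStack-class], list of stacks, or flat list of
#'   [FrameSample-class] objects with world-tagged sensitivities.
#' @param target the reconstruction [VoxelGrid-class].
#' @param nPhases number of cine frames to reconstruct.
#' @param phases explicit cine phases in [0, 2*pi) (overrides
#'   \code{nPhases}).
#' @param model a [WeightModel-class].
#' @param config a [ReconConfig-class].
#' @param verbose print the objective per iteration.
#' @return a [FlowReconstruction-class].
#' @export
reconstructVelocity <- function(frames, target, nPhases = 1L, phases = NULL,
                                model = weightModel(),
                                config = reconConfig(), verbose = FALSE) {
  if (is.null(phases))
    phases <- seq(0, 2 * pi, length.out = nPhases + 1L)[seq_len(nPhases)]
  sys <- .buildSystem(frames, target, model, phases)
  coverage <- .coverageFromSystem(sys, config)
  if (!any(coverage$rank >= config@minEncodingRank & coverage$sampled))
    stop("encoding is rank-deficient everywhere: no voxel is sampled by ",
         config@minEncodingRank, " non-colinear directions")
  lambda <- config@lambda
  delta <- config@delta
  d5 <- c(sys$shape, sys$nh, 3L)

  x <- array(0, dim = d5)
  r <- sys$phi            # residual at V = 0 (forward of zero is zero)
  sse <- sum(sys$p * r^2)
  reg <- if (lambda > 0) velocityRegularizer(x, delta) else list(value = 0)
  obj <- sse + lambda * reg$value
  trace <- obj
  g <- -2 * .systemAdjoint(sys, sys$p * r)
  if (lambda > 0) g <- g + lambda * reg$gradient
  g0norm <- sqrt(sum(g^2))
  dvec <- -g
  .msg(verbose, "iter %3d  objective %.8g (data %.6g, reg %.6g)",
       0L, obj, sse, lambda * reg$value)

  for (it in seq_len(config@maxIter)) {
    gnorm <- sqrt(sum(g^2))
    if (gnorm / max(g0norm, .Machine$double.xmin) < config@gradTol) break
    gd <- sum(g * dvec)
    if (gd >= 0) {      # not a descent direction: steepest-descent restart
      dvec <- -g
      gd <- -gnorm^2
    }
    qd <- .systemForward(sys, dvec)
    b <- sum(sys$p * r * qd)
    c2 <- sum(sys$p * qd^2)
    alpha <- if (c2 > 0 && b > 0) b / c2 else 1
    fTrial <- function(a) {
      dat <- sse - 2 * a * b + a^2 * c2
      rg <- if (lambda > 0)
        velocityRegularizer(x + a * dvec, delta, gradient = FALSE)$value
      else 0
      list(f = dat + lambda * rg, reg = rg)
    }
    ok <- FALSE
    for (ls in 1:40) {
      tr <- fTrial(alpha)
      if (tr$f <= obj + 1e-4 * alpha * gd) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) break     # no admissible step: converged to numeric precision
    x <- x + alpha * dvec
    r <- r - alpha * qd
    sse <- sum(sys$p * r^2)
    regVal <- tr$reg
    obj <- sse + lambda * regVal
    trace <- c(trace, obj)
    gNew <- -2 * .systemAdjoint(sys, sys$p * r)
    if (lambda > 0) {
      reg <- velocityRegularizer(x, delta)
      gNew <- gNew + lambda * reg$gradient
      regVal <- reg$value
    }
    beta <- if (it %% 10L == 0L) 0 else
      max(0, sum(gNew * (gNew - g)) / max(sum(g * g), .Machine$double.xmin))
    dvec <- -gNew + beta * dvec
    g <- gNew
    .msg(verbose, "iter %3d  objective %.8g (data %.6g, reg %.6g, step %.3g)",
         it, obj, sse, lambda * regVal, alpha)
  }

  vol <- new("CineVelocityVolume", values = x, grid = target,
             phases = phases)
  new("FlowReconstruction", volume = vol, objective = trace,
      dataTerm = sse,
      regTerm = velocityRegularizer(x, delta, gradient = FALSE)$value,
      coverage = coverage)
}

#' Speed (velocity magnitude) volume
#'
#' Element-wise Euclidean norm of the three velocity component volumes.
#' Non-negative, zero iff all components vanish, and invariant under a
#' joint rotation of the components.
#'
#' @param v a [CineVelocityVolume-class].
#' @return a [CineMagnitudeVolume-class] of |V| in cm/s.
#' @export
speedVolume <- function(v) {
  sp <- sqrt(v@values[, , , , 1]^2 + v@values[, , , , 2]^2 +
               v@values[, , , , 3]^2)
  new("CineMagnitudeVolume",
      values = array(sp, dim = dim(v@values)[1:4]), grid = v@grid,
      phases = v@phases)
}
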