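# Assembly of the scattered-sample linear acquisition model.
#
# Every kept frame pixel becomes one sample row.  The sparse matrix W maps
# target-voxel values to samples via normalized anisotropic-Gaussian PSF
# weights (in slice coordinates); the predicted phase of sample n is
#   phi_hat[n] = sum_h tau[n, h] * sum_q sdir[n, q] * (W %*% V[, q, h])[n]
# with tau the per-frame temporal weights normalized over cine phases and
# sdir the world-frame sensitivity vector of the sample's frame.

.flattenFrames <- function(x) {
  if (is(x, "FrameStack")) return(x@frames)
  if (is(x, "FrameSample")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, .flattenFrames)))
  stop("expected FrameSample, FrameStack, or a list of them")
}

.buildSystem <- function(frames, target, model, phases) {
  frames <- .flattenFrames(frames)
  if (length(frames) == 0L) stop("no frames to reconstruct from")
  tags <- vapply(frames, function(f) f@sensitivity@frame, character(1))
  if (any(tags != "world"))
    stop("frames carry stack-frame sensitivities; apply ",
         "correctGradientMoments() before reconstruction")
  wts <- vapply(frames, function(f) f@frameWeight, numeric(1))
  if (all(wts == 0)) stop("all frame weights are zero")
  if (any(wts == 0)) {
    warning(sum(wts == 0), " frame(s) with zero weight dropped")
    frames <- frames[wts > 0]
  }
  nh <- length(phases)
  s <- target@shape
  nvox <- prod(s)
  r <- model@supportRadius
  off <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
  nOff <- nrow(off)
  tlin <- target@affine[1:3, 1:3]
  torig <- target@affine[1:3, 4]

  iL <- vector("list", length(frames)); jL <- iL; xL <- iL
  phiL <- iL; keepL <- iL
  nKept <- integer(length(frames))
  sdirF <- matrix(0, length(frames), 3L)
  tauF <- matrix(0, length(frames), nh)
  pF <- numeric(length(frames))

  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    g2 <- fr@grid2d
    n1 <- g2@shape[1]; n2 <- g2@shape[2]
    n <- n1 * n2
    pix <- cbind(rep.int(seq_len(n1) - 1L, n2),
                 rep(seq_len(n2) - 1L, each = n1), 0L)
    p <- applyTransform(fr@transform, worldCoords(g2, pix))
    fidx <- sweep(p, 2L, torig) %*% t(solve(tlin))
    base <- round(fidx)
    # expand samples x offsets
    repS <- rep(seq_len(n), nOff)
    M <- base[repS, , drop = FALSE] + off[rep(seq_len(nOff), each = n), ,
                                          drop = FALSE]
    valid <- M[, 1] >= 0 & M[, 1] < s[1] & M[, 2] >= 0 & M[, 2] < s[2] &
             M[, 3] >= 0 & M[, 3] < s[3]
    if (r == 0L) {
      w <- as.numeric(valid)
    } else {
      dW <- M %*% t(tlin)
      dW <- sweep(dW, 2L, -torig) - p[repS, , drop = FALSE]
      Rtot <- fr@transform@rotation %*%
        sweep(g2@affine[1:3, 1:3], 2L, g2@spacing, "/")
      dS <- dW %*% Rtot
      sg <- .psfSigmas(model, g2@spacing)
      w <- exp(-0.5 * ((dS[, 1] / sg[1])^2 + (dS[, 2] / sg[2])^2 +
                       (dS[, 3] / sg[3])^2))
      w[!valid] <- 0
    }
    W <- matrix(w, n, nOff)
    if (r > 0L && model@weightTrim > 0) {
      mc <- max.col(W, ties.method = "first")
      rowMax <- W[cbind(seq_len(n), mc)]
      W[W < model@weightTrim * rowMax] <- 0
    }
    rs <- rowSums(W)
    kept <- which(rs > 0)
    nKept[k] <- length(kept)
    if (length(kept) == 0L) next
    rankOf <- integer(n)
    rankOf[kept] <- seq_along(kept)
    nz <- which(W > 0)
    sLoc <- ((nz - 1L) %% n) + 1L
    Mi <- M[, 1]; Mj <- M[, 2]; Mk <- M[, 3]
    dim(Mi) <- c(n, nOff); dim(Mj) <- c(n, nOff); dim(Mk) <- c(n, nOff)
    voxLin <- 1L + Mi[nz] + s[1] * (Mj[nz] + s[2] * Mk[nz])
    iL[[k]] <- rankOf[sLoc]
    jL[[k]] <- as.integer(voxLin)
    xL[[k]] <- W[nz] / rs[sLoc]
    phiL[[k]] <- as.numeric(fr@phase)[kept]
    keepL[[k]] <- kept
    sdirF[k, ] <- fr@sensitivity@s
    g <- temporalWeight(fr@cardiacPhase, phases, model)
    tauF[k, ] <- g / sum(g)
    pF[k] <- fr@frameWeight
  }
  if (sum(nKept) == 0L)
    stop("no frame sample falls inside the target grid")
  offs <- c(0L, cumsum(nKept))
  ii <- unlist(lapply(seq_along(frames),
                      function(k) if (nKept[k]) iL[[k]] + offs[k]))
  jj <- unlist(jL)
  xx <- unlist(xL)
  rm(iL, jL, xL)
  Ns <- sum(nKept)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(Ns, nvox))
  rm(ii, jj, xx)
  frameIdx <- rep.int(seq_along(frames), nKept)
  list(W = W,
       phi = unlist(phiL),
       p = pF[frameIdx],
       sdir = sdirF[frameIdx, , drop = FALSE],
       tau = tauF[frameIdx, , drop = FALSE],
       frameIdx = frameIdx, keep = keepL, nKept = nKept,
       frames = frames, shape = s, nvox = nvox, nh = nh, phases = phases)
}

.systemForward <- function(sys, varr) {
  pred <- numeric(length(sys$phi))
  for (h in seq_len(sys$nh)) {
    th <- sys$tau[, h]
    if (max(th) < 1e-10) next
    for (q in 1:3) {
      v <- as.numeric(varr[, , , h, q])
      pred <- pred + th * sys$sdir[, q] * as.numeric(sys$W %*% v)
    }
  }
  pred
}

.systemAdjoint <- function(sys, w) {
  out <- array(0, dim = c(sys$shape, sys$nh, 3L))
  for (h in seq_len(sys$nh)) {
    wh <- w * sys$tau[, h]
    if (max(abs(wh)) == 0) next
    for (q in 1:3)
      out[, , , h, q] <- array(
        as.numeric(Matrix::crossprod(sys$W, wh * sys$sdir[, q])),
        dim = sys$shape)
  }
  out
}

#' Predict phase images from a velocity volume
#'
#' Applies the linear acquisition model: each frame pixel's predicted phase
#' is the temporally weighted, PSF-weighted projection of the cine velocity
#' field onto the frame's world-frame sensitivity.  Linear in the velocity
#' volume; a zero volume predicts zero phase everywhere.
#'
#' @param v a [CineVelocityVolume-class].
#' @param frames a [FrameStack-class], list of stacks, or list of
#'   [FrameSample-class] with world-tagged sensitivities (see
#'   [correctGradientMoments()]).
#' @param model a [WeightModel-class].
#' @return list of predicted phase matrices, one per frame; pixels whose
#'   PSF support misses the target grid are \code{NA}.
#' @export
predictPhase <- function(v, frames, model = weightModel()) {
  sys <- .buildSystem(frames, v@grid, model, v@phases)
  pred <- .systemForward(sys, v@values)
  out <- vector("list", length(sys$keep))
  offs <- c(0L, cumsum(sys$nKept))
  for (k in seq_along(sys$keep)) {
    fr <- sys$frames[[k]]
    img <- matrix(NA_real_, nrow(fr@phase), ncol(fr@phase))
    if (sys$nKept[k])
      img[sys$keep[[k]]] <- pred[(offs[k] + 1L):offs[k + 1L]]
    out[[k]] <- img
  }
  out
}

#' Phase residuals and weighted sum of squared errors
#'
#' e = acquired - predicted per pixel; SSE is the frame-weight-weighted sum
#' of squared residuals.  Frames with zero outlier weight contribute
#' nothing; \code{NA} predictions (no grid support) are excluded.
#'
#' @param frames the frames the prediction was made for.
#' @param predicted list of predicted phase matrices from [predictPhase()].
#' @return list with \code{errors} (list of matrices) and \code{sse}.
#' @export
phaseResiduals <- function(frames, predicted) {
  frames <- .flattenFrames(frames)
  stopifnot(length(frames) == length(predicted))
  errors <- vector("list", length(frames))
  sse <- 0
  for (k in seq_along(frames)) {
    e <- frames[[k]]@phase - predicted[[k]]
    errors[[k]] <- e
    sse <- sse + frames[[k]]@frameWeight * sum(e^2, na.rm = TRUE)
  }
  list(errors = errors, sse = sse)
}
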