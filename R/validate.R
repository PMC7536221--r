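#' Recovered per-pipe peak speeds
#'
#' For every antiparallel pipe pair of a phantom, computes the
#' cross-sectional maximum of the speed volume in each pipe (voxels binned
#' by their projection onto the pipe axis, 1 bin per mm) and reports the
#' median over all cross-sections of both pipes in the pair.
#'
#' @param speed 3D speed array (one cardiac frame of [speedVolume()]).
#' @param labels pipe label array from [buildPhantom()].
#' @param spec the [PhantomSpec-class].
#' @param trimEnds drop this many end cross-sections per pipe (partial
#'   pipe cross-sections at the volume boundary).
#' @return data.frame with one row per pair: \code{truePeak} (cm/s) and
#'   \code{recovered} (cm/s).
#' @export
pipePeakSpeeds <- function(speed, labels, spec, trimEnds = 2L) {
  peaks <- vapply(spec@pipes, function(p) p@peakSpeed, numeric(1))
  pairs <- sort(unique(abs(peaks)))
  centers <- voxelCenters(spec@grid)
  out <- data.frame(truePeak = pairs, recovered = NA_real_)
  for (ip in seq_along(pairs)) {
    maxima <- numeric()
    for (p in which(abs(peaks) == pairs[ip])) {
      pipe <- spec@pipes[[p]]
      sel <- which(labels == p)
      if (!length(sel)) next
      proj <- as.numeric(sweep(centers[sel, , drop = FALSE], 2L,
                               pipe@center) %*% pipe@axis)
      bin <- round(proj)
      mx <- tapply(speed[sel], bin, max)
      if (trimEnds > 0L && length(mx) > 2L * trimEnds)
        mx <- mx[(trimEnds + 1L):(length(mx) - trimEnds)]
      maxima <- c(maxima, as.numeric(mx))
    }
    out$recovered[ip] <- stats::median(maxima)
  }
  out
}

#' End-to-end simulated phantom validation experiment
#'
#' Runs the full pipeline on the digital six-pipe phantom: render ground
#' truth, simulate the five-stack acquisition with additive phase noise,
#' background-correct each stack, reorient the gradient first moments,
#' reconstruct the velocity volume by regularized conjugate gradient,
#' apply the velocity drift correction, and compare against the ground
#' truth within the pipes.
#'
#' @param seed RNG seed for the simulated noise.
#' @param noiseSigma phase noise standard deviation, rad.
#' @param gridSize phantom grid extent (voxels); the reconstruction target
#'   is the phantom grid itself.
#' @param spacing voxel size, mm.
#' @param config a [ReconConfig-class].
#' @param model a [WeightModel-class].
#' @param frameTransforms optional per-stack lists of per-frame
#'   [RigidTransform-class] objects (motion experiments).
#' @param stackSubset indices of the default five stacks to use.
#' @param backgroundCorrect,driftCorrect toggle the correction stages.
#' @param keepVolumes keep the reconstructed and truth volumes in the
#'   returned report.
#' @param verbose print solver progress.
#' @return list with per-pipe peak recovery (\code{peaks}), component
#'   biases and nRMSEs (percent), overall RMS velocity error (cm/s),
#'   flagged-voxel fractions, the flow-conservation comparison of two
#'   cross-sections of the +100 cm/s pipe, and solver diagnostics.
#' @export
validatePhantomExperiment <- function(seed = 1L, noiseSigma = 0.10,
                                      gridSize = 96, spacing = 1,
                                      config = reconConfig(),
                                      model = weightModel(),
                                      frameTransforms = NULL,
                                      stackSubset = 1:5,
                                      backgroundCorrect = TRUE,
                                      driftCorrect = TRUE,
                                      keepVolumes = FALSE,
                                      verbose = FALSE) {
  spec <- defaultPhantom(gridSize = gridSize, spacing = spacing,
                         noiseSigma = noiseSigma, seed = seed)
  plan <- defaultStackPlan(spec)[stackSubset]
  if (!is.null(frameTransforms)) frameTransforms <-
    frameTransforms[stackSubset]
  .msg(verbose, "simulating %d stacks at %d^3, noise sd %.3g rad",
       length(plan), gridSize, noiseSigma)
  sim <- simulatePhantomAcquisition(spec, plan,
                                    frameTransforms = frameTransforms)
  mag <- phantomMagnitude(spec, sim$labels)
  nb <- nonbloodMask(mag)
  stacks <- sim$stacks
  if (backgroundCorrect) {
    .msg(verbose, "background phase correction (%d stacks)", length(stacks))
    stacks <- lapply(stacks, backgroundCorrectStack, fitMask = nb)
  }
  stacks <- lapply(stacks, correctGradientMoments)
  rec <- reconstructVelocity(stacks, spec@grid, config = config,
                             model = model, verbose = verbose)
  vol <- rec@volume
  if (driftCorrect) {
    .msg(verbose, "velocity drift correction")
    vol <- velocityDriftCorrect(vol, nb)
  }
  truth <- sim$truth
  labels <- sim$labels
  pipeSel <- which(labels > 0L)
  speed <- speedVolume(vol)@values[, , , 1]
  speedTruth <- speedVolume(truth)@values[, , , 1]
  peaks <- pipePeakSpeeds(speed, labels, spec)
  comp <- c("x", "y", "z")
  bias <- nr <- stats::setNames(numeric(3), comp)
  for (q in 1:3) {
    est <- vol@values[, , , 1, q][pipeSel]
    ref <- truth@values[, , , 1, q][pipeSel]
    bias[q] <- biasPercent(est, ref)
    nr[q] <- as.numeric(nrmse(est, ref))
  }
  nrSpeed <- as.numeric(nrmse(speed[pipeSel], speedTruth[pipeSel]))
  err2 <- 0
  for (q in 1:3)
    err2 <- err2 + mean((vol@values[, , , 1, q][pipeSel] -
                           truth@values[, , , 1, q][pipeSel])^2)
  rms <- sqrt(err2)
  # flow conservation: two interior cross-sections of the +100 cm/s pipe
  pipePlus <- spec@pipes[[which.max(vapply(spec@pipes,
                                           function(p) p@peakSpeed,
                                           numeric(1)))]]
  half <- gridSize * spacing / 2
  roiA <- planarROI(pipePlus@center + pipePlus@axis * (-half / 2),
                    pipePlus@axis, radius = pipePlus@radius + 2,
                    spacing = 1.25)
  roiB <- planarROI(pipePlus@center + pipePlus@axis * (half / 2),
                    pipePlus@axis, radius = pipePlus@radius + 2,
                    spacing = 1.25)
  qA <- roiFlow(vol, roiA)@meanFlow
  qB <- roiFlow(vol, roiB)@meanFlow
  report <- list(
    seed = seed, noiseSigma = noiseSigma, gridSize = gridSize,
    nStacks = length(plan),
    peaks = peaks,
    biasPercent = bias,
    nrmsePercent = c(nr, speed = nrSpeed),
    rmsErrorCmS = rms,
    flaggedFractionPipes = mean(rec@coverage$flagged[pipeSel]),
    flaggedFractionTotal = mean(rec@coverage$flagged),
    flowCrossSectionA = qA, flowCrossSectionB = qB,
    flowConservationPercent = 100 * abs(qA - qB) / mean(c(qA, qB)),
    objective = rec@objective,
    dataTerm = rec@dataTerm, regTerm = rec@regTerm,
    lambda = config@lambda)
  if (keepVolumes) {
    report$volume <- vol
    report$truth <- truth
    report$labels <- labels
    report$coverage <- rec@coverage
  }
  report
}
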