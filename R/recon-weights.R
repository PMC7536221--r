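#' Construct a spatio-temporal weight model
#'
#' @param psfFwhmInplane in-plane PSF FWHM in mm; \code{NA} (default)
#'   derives 1.2 x the slice in-plane spacing per frame.
#' @param psfFwhmThrough through-slice PSF FWHM in mm; \code{NA} (default)
#'   derives the slice thickness per frame.
#' @param temporalSigma cardiac-phase kernel width in rad.  The default
#'   corresponds to a 72 ms acquired frame on a typical 450 ms fetal R-R
#'   interval: 2*pi * 0.072 / 0.45.
#' @param supportRadius PSF support half-width in target voxels; 0 gives
#'   nearest-voxel (delta) weighting.
#' @param weightTrim relative PSF weight below which entries are dropped.
#' @return a [WeightModel-class].
#' @export
weightModel <- function(psfFwhmInplane = NA_real_,
                        psfFwhmThrough = NA_real_,
                        temporalSigma = 2 * pi * 0.072 / 0.45,
                        supportRadius = 2L, weightTrim = 0.01) {
  new("WeightModel", psfFwhmInplane = as.numeric(psfFwhmInplane),
      psfFwhmThrough = as.numeric(psfFwhmThrough),
      temporalSigma = temporalSigma,
      supportRadius = as.integer(supportRadius), weightTrim = weightTrim)
}

#' Construct a reconstruction configuration
#'
#' @param lambda regularization weight; the default puts the data and
#'   regularization terms of the default noisy phantom problem within one
#'   order of magnitude of each other.
#' @param delta Charbonnier edge-preservation scale, cm/s.
#' @param maxIter maximum conjugate-gradient iterations.
#' @param gradTol relative gradient-norm stopping tolerance.
#' @param minEncodingRank minimum per-voxel encoding rank not to be flagged.
#' @param conditionLimit per-voxel condition-number flag limit.
#' @return a [ReconConfig-class].
#' @export
reconConfig <- function(lambda = 0.1, delta = 30, maxIter = 60L,
                        gradTol = 1e-6, minEncodingRank = 3L,
                        conditionLimit = 100) {
  new("ReconConfig", lambda = lambda, delta = delta,
      maxIter = as.integer(maxIter), gradTol = gradTol,
      minEncodingRank = as.integer(minEncodingRank),
      conditionLimit = conditionLimit)
}

#' Construct cardiac timing metadata
#'
#' @param rrIntervals named numeric: R-R interval duration in s per slice.
#' @param triggerOffsets named numeric: trigger time in s per slice;
#'   defaults to 0 for every slice in \code{rrIntervals}.
#' @return a [CardiacTiming-class].
#' @export
cardiacTiming <- function(rrIntervals, triggerOffsets = NULL) {
  if (is.null(triggerOffsets)) {
    triggerOffsets <- rep(0, length(rrIntervals))
    names(triggerOffsets) <- names(rrIntervals)
  }
  new("CardiacTiming", rrIntervals = rrIntervals,
      triggerOffsets = triggerOffsets)
}

#' Map an acquisition time to a cardiac phase
#'
#' theta = 2*pi * ((t - trigger) mod RR) / RR, using the R-R interval and
#' trigger offset of the frame's slice.
#'
#' @param tAcq acquisition time(s), s.
#' @param timing a [CardiacTiming-class].
#' @param sliceId slice identifier (matched against the timing names).
#' @return cardiac phase(s) in [0, 2*pi).
#' @export
assignCardiacPhase <- function(tAcq, timing, sliceId) {
  key <- as.character(sliceId)
  if (!key %in% names(timing@rrIntervals))
    stop("no cardiac timing available for slice \"", key, "\"")
  rr <- timing@rrIntervals[[key]]
  trig <- timing@triggerOffsets[[key]]
  2 * pi * (((tAcq - trig) %% rr) / rr) %% (2 * pi)
}

#' Temporal weight between cardiac phases
#'
#' Wrapped-Gaussian kernel exp(-d^2 / (2 sigma^2)) on the wrapped angular
#' distance between an acquired frame's phase and a reconstructed cine
#' phase.  Equals 1 at zero distance and is symmetric.
#'
#' @param thetaK acquired frame phase(s), rad.
#' @param thetaH cine frame phase(s), rad.
#' @param model a [WeightModel-class].
#' @return weight(s) in (0, 1].
#' @export
temporalWeight <- function(thetaK, thetaH, model = weightModel()) {
  d <- .wrappedDistance(thetaK, thetaH)
  exp(-d^2 / (2 * model@temporalSigma^2))
}

# Per-frame PSF sigmas in slice coordinates (mm).
.psfSigmas <- function(model, sliceSpacing) {
  fwIn <- if (is.na(model@psfFwhmInplane)) 1.2 * sliceSpacing[1:2]
          else rep(model@psfFwhmInplane, 2L)
  fwTh <- if (is.na(model@psfFwhmThrough)) sliceSpacing[3]
          else model@psfFwhmThrough
  .fwhmToSigma(c(fwIn, fwTh))
}

#' Spatial PSF weights of one acquired sample
#'
#' Evaluates the anisotropic Gaussian point spread function of a single
#' frame voxel (already mapped to world space by the frame transform) at
#' the target-grid voxel centers within the support radius, normalized to
#' sum 1.  The PSF is anisotropic in the \emph{slice} coordinate frame:
#' in-plane FWHM 1.2 x in-plane spacing, through-slice FWHM = slice
#' thickness (unless overridden in the model).
#'
#' @param center world position of the sample, mm.
#' @param target the reconstruction [VoxelGrid-class].
#' @param model a [WeightModel-class].
#' @param sliceRotation 3x3 rotation whose columns are the slice axes in
#'   world coordinates (frame transform already applied).
#' @param sliceSpacing numeric(3) slice voxel size, mm.
#' @return data.frame with 0-based voxel indices \code{i}, \code{j},
#'   \code{k}, the linear index \code{voxel} and \code{weight} (summing to
#'   1); zero rows if the sample has no support inside the target grid.
#' @export
spatialWeights <- function(center, target, model = weightModel(),
                           sliceRotation = diag(3),
                           sliceSpacing = target@spacing) {
  r <- model@supportRadius
  f <- indexCoords(target, center)
  base <- round(f)
  off <- as.matrix(expand.grid(i = -r:r, j = -r:r, k = -r:r))
  m <- sweep(off, 2L, base, "+")
  s <- target@shape
  valid <- m[, 1] >= 0 & m[, 1] < s[1] & m[, 2] >= 0 & m[, 2] < s[2] &
           m[, 3] >= 0 & m[, 3] < s[3]
  m <- m[valid, , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      voxel = integer(), weight = numeric()))
  if (r == 0L) {
    w <- 1
  } else {
    dW <- sweep(worldCoords(target, m), 2L, as.numeric(center))
    dS <- dW %*% sliceRotation
    sg <- .psfSigmas(model, sliceSpacing)
    w <- exp(-0.5 * ((dS[, 1] / sg[1])^2 + (dS[, 2] / sg[2])^2 +
                     (dS[, 3] / sg[3])^2))
    keep <- w >= model@weightTrim * max(w)
    m <- m[keep, , drop = FALSE]
    w <- w[keep]
    w <- w / sum(w)
  }
  data.frame(i = m[, 1], j = m[, 2], k = m[, 3],
             voxel = 1 + m[, 1] + s[1] * (m[, 2] + s[2] * m[, 3]),
             weight = w)
}
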