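#' Construct a planar cross-sectional ROI
#'
#' A circular (or custom) region on a plane perpendicular to a vessel,
#' sampled on a regular in-plane lattice.  Default sample spacing is
#' 1.25 mm, matching the reconstructed voxel size of the framework.
#'
#' @param origin ROI center, world mm.
#' @param normal plane normal (vessel direction); normalized internally.
#' @param radius ROI radius, mm (ignored when \code{offsets} is given).
#' @param spacing in-plane sample spacing, mm.
#' @param offsets optional explicit n x 2 matrix of in-plane sample
#'   coordinates (mm) replacing the circular lattice.
#' @return a [PlanarROI-class].
#' @export
planarROI <- function(origin, normal, radius, spacing = 1.25,
                      offsets = NULL) {
  n <- normal / sqrt(sum(normal^2))
  seed <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  if (is.null(offsets)) {
    m <- ceiling(radius / spacing)
    gridPts <- as.matrix(expand.grid(a = (-m:m) * spacing,
                                     b = (-m:m) * spacing))
    # a sample belongs to the ROI iff its center lies inside the contour
    gridPts <- gridPts[rowSums(gridPts^2) <= radius^2, , drop = FALSE]
    offsets <- gridPts
  }
  new("PlanarROI", origin = as.numeric(origin), normal = n, uAxis = u,
      vAxis = v, offsets = as.matrix(offsets), spacing = spacing)
}

#' ROI flow curve from a velocity (or speed) volume
#'
#' Voxel-wise blood flow is the product of the velocity magnitude |V| and
#' the sample area; vessel flow per cardiac phase is the sum over all ROI
#' samples, with |V| sampled trilinearly at each sample point:
#' Q_h = sum |V|(sample, h) * A.  Units: cm/s times cm^2 gives ml/s.
#' Optionally the through-plane component v . n (signed) replaces |V|.
#'
#' @param x a [CineVelocityVolume-class] or a precomputed speed
#'   [CineMagnitudeVolume-class].
#' @param roi a [PlanarROI-class]; it must intersect the volume.
#' @param weightKg optional body weight for normalized mean flow
#'   (ml/min/kg).
#' @param normalComponent if TRUE (and \code{x} is a velocity volume), use
#'   the signed through-plane component instead of |V|.
#' @return a [FlowCurve-class] in ml/s per cardiac phase.
#' @examples
#' # uniform 1 cm/s over a 1 cm^2 ROI integrates to 1 ml/s
#' @export
roiFlow <- function(x, roi, weightKg = NULL, normalComponent = FALSE) {
  pts <- sweep(roi@offsets[, 1, drop = FALSE] %*% rbind(roi@uAxis) +
                 roi@offsets[, 2, drop = FALSE] %*% rbind(roi@vAxis),
               2L, -roi@origin)
  if (normalComponent && !is(x, "CineVelocityVolume"))
    stop("normalComponent requires a velocity volume")
  grid <- geometry(x)
  idx <- indexCoords(grid, pts)
  nh <- length(cardiacPhases(x))
  flow <- numeric(nh)
  areaCm2 <- roi@spacing^2 / 100
  anyInside <- FALSE
  for (h in seq_len(nh)) {
    if (is(x, "CineVelocityVolume")) {
      smp <- .trilinearVelocity(x@values, idx, h = h)
      inside <- smp$inside
      vals <- if (normalComponent) as.numeric(smp$v %*% roi@normal)
              else sqrt(rowSums(smp$v^2))
    } else {
      arr <- x@values[, , , h]
      dim(arr) <- dim(x@values)[1:3]
      v <- .trilinear(arr, idx)
      inside <- !is.na(v)
      vals <- ifelse(inside, v, 0)
    }
    anyInside <- anyInside || any(inside)
    flow[h] <- sum(vals[inside]) * areaCm2
  }
  if (!anyInside) stop("ROI lies entirely outside the volume")
  meanFlow <- mean(flow)
  new("FlowCurve", flow = flow, phases = cardiacPhases(x),
      meanFlow = meanFlow,
      normalizedFlow = if (is.null(weightKg)) NA_real_
                       else normalizeFlow(meanFlow, weightKg))
}

#' Normalize mean flow to body weight
#'
#' @param meanFlow mean flow, ml/s.
#' @param weightKg body weight, kg (> 0).
#' @return normalized flow, ml/min/kg.
#' @export
normalizeFlow <- function(meanFlow, weightKg) {
  if (!is.finite(weightKg) || weightKg <= 0)
    stop("weight must be a positive number of kg")
  meanFlow * 60 / weightKg
}

#' Percentage bias between paired estimates and reference
#'
#' 100 * mean(est - ref) / mean(|ref|).
#'
#' @param est,ref paired numeric vectors on the same support.
#' @return bias in percent.
#' @export
biasPercent <- function(est, ref) {
  stopifnot(length(est) == length(ref))
  denom <- mean(abs(ref))
  if (denom == 0) stop("zero reference mean: bias is undefined")
  100 * mean(est - ref) / denom
}

#' Normalized root mean square error
#'
#' RMSE normalized to the central 99-percentile range of the reference
#' (quantiles 0.005 to 0.995), in percent.
#'
#' @param est,ref paired numeric vectors.
#' @return nRMSE in percent, with the range convention recorded in the
#'   \code{"range"} attribute.
#' @export
nrmse <- function(est, ref) {
  stopifnot(length(est) == length(ref))
  qs <- stats::quantile(ref, c(0.005, 0.995), names = FALSE)
  rng <- qs[2] - qs[1]
  if (rng <= 0) stop("degenerate reference range: nRMSE is undefined")
  out <- 100 * sqrt(mean((est - ref)^2)) / rng
  attr(out, "range") <- c(p0.5 = qs[1], p99.5 = qs[2])
  out
}

#' Bland-Altman agreement of paired means
#'
#' Per-pair percentage difference d_i = 100 * 2 (a_i - b_i) / (a_i + b_i);
#' bias is the mean of d and its spread the sample standard deviation.
#'
#' @param a,b paired measurements (n >= 2); no pair may sum to zero.
#' @return list with \code{bias} and \code{sd} in percent and the
#'   per-pair differences \code{d}.
#' @export
blandAltman <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L)
    stop("Bland-Altman needs at least 2 pairs (SD undefined for n = 1)")
  if (any(a + b == 0)) stop("pair with zero mean: difference undefined")
  d <- 100 * 2 * (a - b) / (a + b)
  list(bias = mean(d), sd = stats::sd(d), d = d)
}
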