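#' Wrap phase to (-pi, pi]
#'
#' Maps any phase to its principal value, with the convention that the upper
#' boundary pi is included (so a velocity exactly at VENC maps to +pi).
#' Idempotent; congruent to the input modulo 2*pi.
#'
#' @param phi phase(s) in rad.
#' @return wrapped phase(s) in (-pi, pi].
#' @export
wrapPhase <- function(phi) {
  phi - 2 * pi * ceiling((phi - pi) / (2 * pi))
}

#' Build a sensitivity from VENC and direction
#'
#' Inverse of the VENC definition: |s| = pi / VENC along the given unit
#' direction.
#'
#' @param venc velocity-encoding limit in cm/s (> 0).
#' @param direction unit 3-vector (|direction| = 1 within 1e-8).
#' @param frame frame tag, \code{"stack"} (default) or \code{"world"}.
#' @return an [EncodingSensitivity-class].
#' @examples
#' s <- sensitivityFromVenc(159, c(1, 0, 0))
#' venc(s)
#' @export
sensitivityFromVenc <- function(venc, direction, frame = "stack") {
  if (!is.finite(venc) || venc <= 0)
    stop("venc must be a positive speed in cm/s")
  n <- sqrt(sum(direction^2))
  if (abs(n - 1) > 1e-8)
    stop("direction must be a unit vector")
  new("EncodingSensitivity", s = pi / venc * direction / n, frame = frame)
}

#' Velocity to phase (forward encoding model)
#'
#' The phase accrued in a voxel is the dot product of the velocity-encoding
#' sensitivity (gyromagnetic ratio times gradient first moment) with the
#' local velocity vector, wrapped to (-pi, pi].  Velocity and sensitivity
#' must be expressed in the same coordinate frame.
#'
#' @param v velocity 3-vector in cm/s, or an n x 3 matrix of velocities.
#' @param sensitivity an [EncodingSensitivity-class].
#' @param frame the frame \code{v} is expressed in; must match the
#'   sensitivity's frame tag.
#' @return phase(s) in rad, wrapped to (-pi, pi].
#' @examples
#' s <- sensitivityFromVenc(159, c(1, 0, 0), frame = "world")
#' phaseFromVelocity(c(100, 0, 0), s, frame = "world")  # pi * 100 / 159
#' @export
phaseFromVelocity <- function(v, sensitivity, frame = "world") {
  if (!identical(frame, sensitivity@frame))
    stop(sprintf(
      "frame mismatch: velocity in \"%s\" frame, sensitivity in \"%s\" frame",
      frame, sensitivity@frame))
  if (is.matrix(v)) wrapPhase(as.numeric(v %*% sensitivity@s))
  else wrapPhase(sum(v * sensitivity@s))
}

#' Reorient a sensitivity under rigid motion
#'
#' When motion rotates an imaging frame, the gradient first moments (hence
#' the sensitivity) rotate with it; the rotated slice remains a valid
#' projection of the velocity field along the rotated direction.  Only the
#' rotation part of the transform acts; |s| (and so VENC) is invariant.
#'
#' @param sensitivity an [EncodingSensitivity-class] in the stack frame.
#' @param transform the frame's motion-correction [RigidTransform-class].
#' @return the reoriented [EncodingSensitivity-class], tagged \code{"world"}.
#' @export
rotateSensitivity <- function(sensitivity, transform) {
  new("EncodingSensitivity",
      s = as.numeric(transform@rotation %*% sensitivity@s), frame = "world")
}

#' Apply gradient-moment correction to frames
#'
#' Recomputes each frame's velocity-encoding sensitivity under its rigid
#' motion-correction transform (see [rotateSensitivity()]), leaving all other
#' frame data untouched.  Reconstruction requires world-frame sensitivities.
#'
#' @param x a [FrameStack-class] or list of [FrameSample-class] objects.
#' @return the same container with world-tagged sensitivities.
#' @export
correctGradientMoments <- function(x) {
  fixup <- function(fr) {
    if (fr@sensitivity@frame == "stack")
      fr@sensitivity <- rotateSensitivity(fr@sensitivity, fr@transform)
    fr
  }
  if (is(x, "FrameStack")) {
    x@frames <- lapply(x@frames, fixup)
    x
  } else if (is(x, "FrameSample")) {
    fixup(x)
  } else {
    lapply(x, correctGradientMoments)
  }
}
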