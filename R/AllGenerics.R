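#' Geometry accessor
#'
#' Returns the [VoxelGrid-class] an object lives on.
#' @param x an object with a grid.
#' @return a [VoxelGrid-class].
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @describeIn geometry grid of a velocity volume
#' @export
setMethod("geometry", "CineVelocityVolume", function(x) x@grid)

#' @describeIn geometry grid of a magnitude volume
#' @export
setMethod("geometry", "CineMagnitudeVolume", function(x) x@grid)

#' @describeIn geometry grid of a mask
#' @export
setMethod("geometry", "VolumeMask", function(x) x@grid)

#' @describeIn geometry 3D grid of a stack of frames
#' @export
setMethod("geometry", "FrameStack", function(x) x@stackGrid)

#' @describeIn geometry slice grid of a single frame
#' @export
setMethod("geometry", "FrameSample", function(x) x@grid2d)

#' Velocity-encoding limit of a sensitivity
#'
#' VENC is the speed along the sensitivity direction that produces a phase
#' of pi: VENC = pi / |s|.
#' @param x an [EncodingSensitivity-class].
#' @return VENC in cm/s.
#' @export
setGeneric("venc", function(x) standardGeneric("venc"))

#' @describeIn venc VENC of a sensitivity vector
#' @export
setMethod("venc", "EncodingSensitivity",
  function(x) pi / sqrt(sum(x@s^2)))

#' Raw values accessor
#'
#' Returns the underlying numeric array of a volume-like object: a
#' (nx, ny, nz, nPhases, 3) array for velocity volumes, (nx, ny, nz,
#' nPhases) for magnitude volumes, a logical 3D array for masks and the
#' flow vector for flow curves.
#' @param x the object.
#' @return the underlying array or vector.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @describeIn values velocity component array, cm/s
#' @export
setMethod("values", "CineVelocityVolume", function(x) x@values)

#' @describeIn values magnitude array
#' @export
setMethod("values", "CineMagnitudeVolume", function(x) x@values)

#' @describeIn values logical mask array
#' @export
setMethod("values", "VolumeMask", function(x) x@values)

#' @describeIn values flow per cardiac phase, ml/s
#' @export
setMethod("values", "FlowCurve", function(x) x@flow)

#' Cardiac phases accessor
#' @param x a cine volume or flow curve.
#' @return numeric vector of cardiac phases in [0, 2*pi).
#' @export
setGeneric("cardiacPhases", function(x) standardGeneric("cardiacPhases"))

#' @describeIn cardiacPhases phases of a velocity volume
#' @export
setMethod("cardiacPhases", "CineVelocityVolume", function(x) x@phases)

#' @describeIn cardiacPhases phases of a magnitude volume
#' @export
setMethod("cardiacPhases", "CineMagnitudeVolume", function(x) x@phases)

#' @describeIn cardiacPhases phases of a flow curve
#' @export
setMethod("cardiacPhases", "FlowCurve", function(x) x@phases)

#' Frames accessor
#' @param x a [FrameStack-class].
#' @return list of [FrameSample-class] objects.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @describeIn frames frames of a stack
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @export
setMethod("length", "FrameStack", function(x) length(x@frames))

#' Extract a single frame from a stack
#' @param x a [FrameStack-class].
#' @param i frame index.
#' @return a [FrameSample-class].
#' @export
setMethod("[[", "FrameStack", function(x, i) x@frames[[i]])

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s, spacing %s mm\n",
              paste(object@shape, collapse = " x "),
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat("origin (mm):", format(object@affine[1:3, 4], digits = 4), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%s) mm\n",
              ang * 180 / pi,
              paste(format(object@translation, digits = 4), collapse = ", ")))
})

setMethod("show", "EncodingSensitivity", function(object) {
  cat(sprintf("EncodingSensitivity [%s frame]: VENC %.4g cm/s, direction (%s)\n",
              object@frame, venc(object),
              paste(format(object@s / sqrt(sum(object@s^2)), digits = 3),
                    collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d pipes on a %s grid, phase noise sd %.3g rad\n",
              length(object@pipes),
              paste(object@grid@shape, collapse = " x "), object@noiseSigma))
})

setMethod("show", "FrameStack", function(object) {
  cat(sprintf("FrameStack: %d frames of %s pixels\n", length(object@frames),
              if (length(object@frames))
                paste(dim(object@frames[[1]]@phase), collapse = " x ")
              else "?"))
})

setMethod("show", "CineVelocityVolume", function(object) {
  sp <- sqrt(apply(object@values^2, 1:4, sum))
  cat(sprintf(
    "CineVelocityVolume: %s voxels, %d cardiac phase(s), peak speed %.2f cm/s\n",
    paste(object@grid@shape, collapse = " x "), length(object@phases),
    max(sp)))
})

setMethod("show", "CineMagnitudeVolume", function(object) {
  cat(sprintf("CineMagnitudeVolume: %s voxels, %d cardiac phase(s)\n",
              paste(object@grid@shape, collapse = " x "),
              length(object@phases)))
})

setMethod("show", "FlowCurve", function(object) {
  cat(sprintf("FlowCurve: %d phase(s), mean %.4g ml/s%s\n",
              length(object@flow), object@meanFlow,
              if (is.na(object@normalizedFlow)) ""
              else sprintf(" (%.4g ml/min/kg)", object@normalizedFlow)))
})

setMethod("show", "FlowReconstruction", function(object) {
  cat(sprintf(
    "FlowReconstruction: %d CG iterations, objective %.6g -> %.6g\n",
    length(object@objective) - 1L, object@objective[1],
    object@objective[length(object@objective)]))
  cat(sprintf("  data term %.6g, regularizer %.6g, flagged voxels %.2f%%\n",
              object@dataTerm, object@regTerm,
              100 * mean(object@coverage$flagged)))
  show(object@volume)
})
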