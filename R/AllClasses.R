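#' @import methods
NULL

#' Regular voxel lattice with a world-space affine
#'
#' A \code{VoxelGrid} describes a regular 3D lattice of voxels together with
#' the 4x4 affine that maps 0-based voxel indices to world coordinates in mm.
#' The affine maps the \emph{center} of voxel (0,0,0); the convention follows
#' the NIfTI sform with RAS world axes.  2D slice geometries are represented
#' as grids whose third dimension has extent 1.
#'
#' @slot shape integer(3), number of voxels along each axis (> 0).
#' @slot spacing numeric(3), voxel edge lengths in mm (> 0).
#' @slot affine 4x4 numeric matrix; its 3x3 linear part must have columns
#'   whose norms equal \code{spacing} (i.e. rotation times voxel scaling).
#'
#' @seealso [voxelGrid()], [worldCoords()], [indexCoords()]
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", affine = "matrix"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else {
    lin <- object@affine[1:3, 1:3]
    if (abs(det(lin)) < .Machine$double.eps)
      msg <- c(msg, "affine is singular")
    cn <- sqrt(colSums(lin^2))
    if (length(object@spacing) == 3L &&
        any(abs(cn - object@spacing) > 1e-6 * pmax(1, object@spacing)))
      msg <- c(msg, "affine column norms must equal spacing")
    if (any(abs(object@affine[4, ] - c(0, 0, 0, 1)) > 1e-12))
      msg <- c(msg, "last affine row must be (0,0,0,1)")
  }
  if (length(msg)) msg else TRUE
})

#' Rigid body transform
#'
#' Proper rigid transform (rotation + translation) in world coordinates,
#' used to align acquired image frames with the reconstruction volume.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3) translation in mm.
#'
#' @seealso [rigidTransform()], [applyTransform()], [composeTransforms()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)))
    return("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal (R'R = I)")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det = +1)")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    return("translation must be a finite 3-vector (mm)")
  TRUE
})

#' Velocity-encoding sensitivity
#'
#' The velocity-to-phase sensitivity vector of an acquisition, i.e. the
#' gyromagnetic ratio times the net gradient first moment, in
#' rad per (cm/s).  The phase accrued by a spin moving with velocity v is
#' the dot product of this vector with v.  The velocity-encoding limit is
#' VENC = pi / |s|.
#'
#' The \code{frame} tag records whether the vector is the static,
#' as-prescribed sensitivity of a stack (\code{"stack"}) or has already been
#' reoriented by a frame's motion-correction transform (\code{"world"}).
#'
#' @slot s numeric(3), sensitivity in rad/(cm/s); must be non-zero.
#' @slot frame either \code{"stack"} or \code{"world"}.
#'
#' @seealso [sensitivityFromVenc()], [phaseFromVelocity()],
#'   [rotateSensitivity()], [venc()]
#' @export
setClass("EncodingSensitivity",
  representation(s = "numeric", frame = "character"))

setValidity("EncodingSensitivity", function(object) {
  if (length(object@s) != 3L || any(!is.finite(object@s)))
    return("s must be a finite 3-vector")
  if (sqrt(sum(object@s^2)) <= 0)
    return("|s| must be > 0 (VENC would be infinite)")
  if (length(object@frame) != 1L || !object@frame %in% c("stack", "world"))
    return("frame must be \"stack\" or \"world\"")
  TRUE
})

#' Cylindrical pipe of the digital flow phantom
#'
#' @slot axis unit 3-vector, flow direction.
#' @slot center point on the pipe axis, world mm.
#' @slot radius pipe radius in mm (> 0).
#' @slot peakSpeed signed on-axis peak speed in cm/s.
#' @slot profileSigma standard deviation of the Gaussian flow profile in mm.
#' @export
setClass("PipeSpec",
  representation(axis = "numeric", center = "numeric", radius = "numeric",
                 peakSpeed = "numeric", profileSigma = "numeric"))

setValidity("PipeSpec", function(object) {
  if (length(object@axis) != 3L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    return("axis must be a unit 3-vector")
  if (object@radius <= 0) return("radius must be > 0")
  if (object@profileSigma <= 0) return("profileSigma must be > 0")
  if (length(object@center) != 3L) return("center must be a 3-vector (mm)")
  TRUE
})

#' Digital six-pipe flow phantom specification
#'
#' Parametric description of the simulated flow phantom: a set of straight
#' cylindrical pipes with truncated-Gaussian flow profiles on a voxel grid,
#' plus the phase-noise level and RNG seed used when simulating stacks.
#'
#' @slot pipes list of [PipeSpec-class] objects.
#' @slot grid the [VoxelGrid-class] on which ground truth is rendered.
#' @slot noiseSigma standard deviation of additive Gaussian phase noise, rad.
#' @slot seed integer RNG seed for stack simulation.
#' @seealso [defaultPhantom()], [buildPhantom()]
#' @export
setClass("PhantomSpec",
  representation(pipes = "list", grid = "VoxelGrid",
                 noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!all(vapply(object@pipes, is, logical(1), class2 = "PipeSpec")))
    return("pipes must all be PipeSpec objects")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' One acquired 2D frame of phase-contrast data
#'
#' A single dynamic image frame: phase and magnitude images on a slice
#' geometry, together with the rigid motion-correction transform, the
#' velocity-encoding sensitivity, acquisition time, cardiac phase and the
#' frame outlier-rejection weight inherited from the magnitude cine pipeline.
#'
#' @slot phase matrix of phase values in rad, wrapped to (-pi, pi].
#' @slot magnitude matrix of magnitude values (arbitrary units, >= 0).
#' @slot grid2d slice geometry: a [VoxelGrid-class] with third extent 1.
#' @slot transform the frame's [RigidTransform-class] (identity if static).
#' @slot sensitivity the frame's [EncodingSensitivity-class].
#' @slot tAcq acquisition time in s.
#' @slot cardiacPhase cardiac phase in [0, 2*pi).
#' @slot frameWeight outlier weight in [0, 1]; 0 excludes the frame.
#' @export
setClass("FrameSample",
  representation(phase = "matrix", magnitude = "matrix", grid2d = "VoxelGrid",
                 transform = "RigidTransform",
                 sensitivity = "EncodingSensitivity",
                 tAcq = "numeric", cardiacPhase = "numeric",
                 frameWeight = "numeric"))

setValidity("FrameSample", function(object) {
  msg <- character()
  if (object@grid2d@shape[3] != 1L)
    msg <- c(msg, "grid2d must have unit third dimension")
  if (!all(dim(object@phase) == object@grid2d@shape[1:2]))
    msg <- c(msg, "phase dimensions must match grid2d shape")
  if (!all(dim(object@magnitude) == dim(object@phase)))
    msg <- c(msg, "magnitude and phase dimensions must match")
  if (any(object@phase <= -pi - 1e-9 | object@phase > pi + 1e-9, na.rm = TRUE))
    msg <- c(msg, "phase must be wrapped to (-pi, pi]")
  if (object@frameWeight < 0 || object@frameWeight > 1)
    msg <- c(msg, "frameWeight must lie in [0, 1]")
  if (object@cardiacPhase < 0 || object@cardiacPhase >= 2 * pi)
    msg <- c(msg, "cardiacPhase must lie in [0, 2*pi)")
  if (length(msg)) msg else TRUE
})

#' Stack of acquired frames
#'
#' An ordered collection of [FrameSample-class] objects (typically the slices
#' of one multi-planar stack) together with the 3D geometry of the stack.
#'
#' @slot frames list of [FrameSample-class].
#' @slot stackGrid the stack's 3D [VoxelGrid-class].
#' @seealso [simulateStack()], [readFrameStack()], [writeFrameStack()]
#' @export
setClass("FrameStack",
  representation(frames = "list", stackGrid = "VoxelGrid"))

setValidity("FrameStack", function(object) {
  if (!all(vapply(object@frames, is, logical(1), class2 = "FrameSample")))
    return("frames must all be FrameSample objects")
  TRUE
})

#' Third-order spatial polynomial field
#'
#' Coefficients of a scalar polynomial of total degree <= 3 over centered and
#' scaled world coordinates, used to model smooth background phase offsets
#' and residual velocity drifts.  The monomial basis is
#' \code{x^a y^b z^c, a+b+c <= 3} (20 terms) enumerated in increasing total
#' degree with lexicographic (a, b, c) order within a degree.
#'
#' @slot coefficients numeric(20) in the basis order above.
#' @slot center world point subtracted from coordinates before evaluation.
#' @slot scale scalar mm divisor applied after centering.
#' @seealso [fitPoly3()], [evalPoly3()]
#' @export
setClass("Poly3Field",
  representation(coefficients = "numeric", center = "numeric",
                 scale = "numeric"))

setValidity("Poly3Field", function(object) {
  if (length(object@coefficients) != 20L)
    return("a degree-3 polynomial in 3 variables has 20 coefficients")
  if (length(object@center) != 3L) return("center must be a 3-vector")
  if (length(object@scale) != 1L || object@scale <= 0)
    return("scale must be a positive scalar (mm)")
  TRUE
})

#' Boolean volume mask
#'
#' @slot values logical 3D array.
#' @slot grid the [VoxelGrid-class] the mask lives on.
#' @seealso [nonbloodMask()], [backgroundCorrectStack()]
#' @export
setClass("VolumeMask",
  representation(values = "array", grid = "VoxelGrid"))

setValidity("VolumeMask", function(object) {
  if (!is.logical(object@values) || length(dim(object@values)) != 3L)
    return("values must be a logical 3D array")
  if (!all(dim(object@values) == object@grid@shape))
    return("mask dimensions must match grid shape")
  TRUE
})

#' Cine velocity vector volume
#'
#' The reconstructed field: three Cartesian velocity components (world axes,
#' cm/s) per voxel per cardiac phase, on an isotropic grid.
#'
#' @slot values numeric array of dim (nx, ny, nz, nPhases, 3), cm/s.
#' @slot grid the reconstruction [VoxelGrid-class].
#' @slot phases cardiac phases of the cine frames, strictly increasing in
#'   [0, 2*pi).
#' @seealso [reconstructVelocity()], [speedVolume()]
#' @export
setClass("CineVelocityVolume",
  representation(values = "array", grid = "VoxelGrid", phases = "numeric"))

setValidity("CineVelocityVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 5L || d[5] != 3L)
    return("values must be a (nx, ny, nz, nPhases, 3) array")
  if (!all(d[1:3] == object@grid@shape))
    return("spatial dimensions must match grid shape")
  if (d[4] != length(object@phases) || d[4] < 1L)
    return("fourth dimension must match the number of cardiac phases (>= 1)")
  if (any(!is.finite(object@values)))
    return("velocities must be finite everywhere")
  ph <- object@phases
  if (any(ph < 0 | ph >= 2 * pi) || (length(ph) > 1 && any(diff(ph) <= 0)))
    return("phases must be strictly increasing in [0, 2*pi)")
  TRUE
})

#' Cine magnitude volume
#'
#' @slot values non-negative array of dim (nx, ny, nz, nPhases).
#' @slot grid the [VoxelGrid-class].
#' @slot phases cardiac phases, strictly increasing in [0, 2*pi).
#' @export
setClass("CineMagnitudeVolume",
  representation(values = "array", grid = "VoxelGrid", phases = "numeric"))

setValidity("CineMagnitudeVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L)
    return("values must be a (nx, ny, nz, nPhases) array")
  if (!all(d[1:3] == object@grid@shape))
    return("spatial dimensions must match grid shape")
  if (d[4] != length(object@phases) || d[4] < 1L)
    return("fourth dimension must match the number of cardiac phases (>= 1)")
  if (any(object@values < 0, na.rm = TRUE))
    return("magnitudes must be non-negative")
  TRUE
})

#' Spatio-temporal sample weighting model
#'
#' Parameters of the anisotropic Gaussian point spread function that spreads
#' each acquired slice voxel onto reconstruction-grid voxels, and of the
#' wrapped-Gaussian kernel weighting frames across cardiac phases.  PSF
#' FWHMs set to \code{NA} are derived per frame from the slice geometry
#' (in-plane FWHM = 1.2 x in-plane spacing, through-slice FWHM = slice
#' thickness).
#'
#' @slot psfFwhmInplane in-plane PSF full width at half maximum, mm (or NA).
#' @slot psfFwhmThrough through-slice PSF FWHM, mm (or NA).
#' @slot temporalSigma cardiac-phase kernel width, rad.
#' @slot supportRadius PSF support half-width in target voxels (>= 0);
#'   0 collapses the PSF to nearest-voxel (delta) weighting.
#' @slot weightTrim relative weight below which PSF entries are dropped
#'   before renormalization (sparsity control).
#' @seealso [weightModel()], [spatialWeights()], [temporalWeight()]
#' @export
setClass("WeightModel",
  representation(psfFwhmInplane = "numeric", psfFwhmThrough = "numeric",
                 temporalSigma = "numeric", supportRadius = "integer",
                 weightTrim = "numeric"))

setValidity("WeightModel", function(object) {
  ok <- function(x) is.na(x) || x > 0
  if (!ok(object@psfFwhmInplane) || !ok(object@psfFwhmThrough))
    return("PSF FWHMs must be positive or NA (derive from slice geometry)")
  if (object@temporalSigma <= 0) return("temporalSigma must be > 0")
  if (object@supportRadius < 0L) return("supportRadius must be >= 0")
  if (object@weightTrim < 0 || object@weightTrim >= 1)
    return("weightTrim must lie in [0, 1)")
  TRUE
})

#' Reconstruction configuration
#'
#' @slot lambda regularization weight (>= 0).
#' @slot delta Charbonnier edge-preservation scale, cm/s (> 0).
#' @slot maxIter maximum conjugate-gradient iterations.
#' @slot gradTol relative gradient-norm stopping tolerance.
#' @slot minEncodingRank minimum per-voxel encoding rank not to be flagged.
#' @slot conditionLimit per-voxel condition-number limit not to be flagged.
#' @seealso [reconConfig()], [reconstructVelocity()]
#' @export
setClass("ReconConfig",
  representation(lambda = "numeric", delta = "numeric", maxIter = "integer",
                 gradTol = "numeric", minEncodingRank = "integer",
                 conditionLimit = "numeric"))

setValidity("ReconConfig", function(object) {
  if (object@lambda < 0) return("lambda must be >= 0")
  if (object@delta <= 0) return("delta must be > 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@gradTol <= 0) return("gradTol must be > 0")
  if (object@minEncodingRank < 1L || object@minEncodingRank > 3L)
    return("minEncodingRank must be in 1..3")
  if (object@conditionLimit <= 1) return("conditionLimit must be > 1")
  TRUE
})

#' Cardiac timing metadata
#'
#' R-R interval durations and trigger offsets per acquired slice, used to
#' map acquisition times to cardiac phases.
#'
#' @slot rrIntervals named numeric, R-R durations in s per slice id (> 0).
#' @slot triggerOffsets named numeric, trigger times in s per slice id.
#' @seealso [assignCardiacPhase()]
#' @export
setClass("CardiacTiming",
  representation(rrIntervals = "numeric", triggerOffsets = "numeric"))

setValidity("CardiacTiming", function(object) {
  if (any(object@rrIntervals <= 0)) return("R-R intervals must be > 0")
  if (is.null(names(object@rrIntervals)) ||
      is.null(names(object@triggerOffsets)))
    return("rrIntervals and triggerOffsets must be named by slice id")
  if (!setequal(names(object@rrIntervals), names(object@triggerOffsets)))
    return("rrIntervals and triggerOffsets must cover the same slice ids")
  TRUE
})

#' Planar cross-sectional region of interest
#'
#' A 2D ROI on a plane in world space, represented as a lattice of sample
#' points (in-plane coordinates, mm) on a regular grid of given spacing.
#' Flow is integrated over these samples.
#'
#' @slot origin plane origin, world mm.
#' @slot normal unit plane normal.
#' @slot uAxis,vAxis orthonormal in-plane basis vectors.
#' @slot offsets n x 2 matrix of in-plane sample coordinates, mm.
#' @slot spacing in-plane sample spacing, mm.
#' @seealso [planarROI()], [roiFlow()]
#' @export
setClass("PlanarROI",
  representation(origin = "numeric", normal = "numeric", uAxis = "numeric",
                 vAxis = "numeric", offsets = "matrix", spacing = "numeric"))

setValidity("PlanarROI", function(object) {
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
    return("normal must be a unit vector")
  if (object@spacing <= 0) return("sample spacing must be > 0")
  if (ncol(object@offsets) != 2L || nrow(object@offsets) < 1L)
    return("offsets must be a non-empty n x 2 matrix")
  TRUE
})

#' Cardiac flow curve
#'
#' Blood flow through an ROI per cardiac phase, in ml/s, with the derived
#' mean and (optionally) the weight-normalized mean in ml/min/kg.
#'
#' @slot flow numeric, ml/s per cardiac phase.
#' @slot phases cardiac phases in rad.
#' @slot meanFlow mean of \code{flow}, ml/s.
#' @slot normalizedFlow mean flow normalized to body weight, ml/min/kg
#'   (NA unless a weight was supplied).
#' @seealso [roiFlow()], [normalizeFlow()]
#' @export
setClass("FlowCurve",
  representation(flow = "numeric", phases = "numeric", meanFlow = "numeric",
                 normalizedFlow = "numeric"))

setValidity("FlowCurve", function(object) {
  if (length(object@flow) != length(object@phases))
    return("flow and phases must have equal length")
  TRUE
})

#' Result of a velocity reconstruction
#'
#' Container returned by [reconstructVelocity()]: the reconstructed cine
#' velocity volume, the objective trace of the conjugate-gradient solve, the
#' final data and regularization terms, and the per-voxel coverage summary.
#'
#' @slot volume the reconstructed [CineVelocityVolume-class].
#' @slot objective objective value per accepted CG iteration (index 1 is the
#'   zero-velocity starting point).
#' @slot dataTerm,regTerm weighted sum of squared phase residuals and
#'   (unscaled) regularizer value at the solution.
#' @slot coverage list with per-voxel encoding \code{rank}, \code{condition}
#'   and logical \code{flagged} arrays (see [coverageMap()]).
#' @export
setClass("FlowReconstruction",
  representation(volume = "CineVelocityVolume", objective = "numeric",
                 dataTerm = "numeric", regTerm = "numeric",
                 coverage = "list"))
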