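#' Construct a pipe specification
#'
#' @param axis flow direction (will be normalized; must be non-zero).
#' @param center a point on the pipe axis, world mm.
#' @param radius pipe radius, mm.
#' @param peakSpeed signed on-axis peak speed, cm/s.
#' @param profileSigma Gaussian profile width, mm; defaults to radius / 2.
#' @return a [PipeSpec-class].
#' @export
pipeSpec <- function(axis, center, radius, peakSpeed,
                     profileSigma = radius / 2) {
  axis <- axis / sqrt(sum(axis^2))
  new("PipeSpec", axis = as.numeric(axis), center = as.numeric(center),
      radius = radius, peakSpeed = peakSpeed, profileSigma = profileSigma)
}

#' Truncated-Gaussian pipe flow profile
#'
#' Speed at radial distance d from the pipe axis:
#' peak * exp(-d^2 / (2 sigma^2)) for d <= radius, exactly 0 beyond the
#' pipe wall.  A simple approximation of laminar flow.
#'
#' @param d radial distance(s) from the axis, mm (>= 0).
#' @param pipe a [PipeSpec-class].
#' @return signed speed(s) in cm/s.
#' @export
pipeProfile <- function(d, pipe) {
  if (any(d < 0)) stop("radial distance must be >= 0")
  ifelse(d <= pipe@radius,
         pipe@peakSpeed * exp(-d^2 / (2 * pipe@profileSigma^2)), 0)
}

#' The default six-pipe flow phantom
#'
#' Three antiparallel pipe pairs along the three world axes with peak speeds
#' +/-25 (z pipes), +/-80 (y pipes) and +/-100 cm/s (x pipes), radius 5 mm,
#' Gaussian profile sigma = radius / 2, on a centered isotropic grid
#' (default 96^3 at 1 mm).  Pipe pairs are offset +/-12 mm from the volume
#' center along one perpendicular axis each, which keeps all pipe axes
#' 12 mm apart (no overlap at radius 5 mm).
#'
#' @param gridSize scalar or integer(3) grid extent (voxels).
#' @param spacing voxel size, mm.
#' @param noiseSigma additive phase noise sd used when simulating, rad.
#' @param seed RNG seed recorded in the spec.
#' @param offset pair offset from the center, mm.
#' @param radius pipe radius, mm.
#' @return a [PhantomSpec-class].
#' @export
defaultPhantom <- function(gridSize = 96, spacing = 1, noiseSigma = 0.10,
                           seed = 1L, offset = 12, radius = 5) {
  shape <- rep_len(as.integer(gridSize), 3L)
  # anchor voxel centers on integer multiples of the spacing so that the
  # pipe axes are sampled exactly and the discrete truth attains the
  # nominal peak speeds
  grid <- voxelGrid(shape, spacing, origin = -floor(shape / 2) * spacing)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  pipes <- list(
    pipeSpec(ex, c(0,  offset, 0), radius,  100),
    pipeSpec(ex, c(0, -offset, 0), radius, -100),
    pipeSpec(ey, c(0, 0,  offset), radius,   80),
    pipeSpec(ey, c(0, 0, -offset), radius,  -80),
    pipeSpec(ez, c( offset, 0, 0), radius,   25),
    pipeSpec(ez, c(-offset, 0, 0), radius,  -25))
  new("PhantomSpec", pipes = pipes, grid = grid, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

#' Render the ground-truth velocity volume of a phantom
#'
#' Velocity at each voxel is the pipe profile speed times the pipe axis for
#' the pipe containing the voxel, and (0,0,0) elsewhere.  Voxels claimed by
#' two pipes are an error (pipes must not overlap).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with \code{truth} (a single-phase [CineVelocityVolume-class])
#'   and \code{labels} (integer array: 0 = background, p = pipe index).
#' @export
buildPhantom <- function(spec) {
  grid <- spec@grid
  P <- voxelCenters(grid)
  n <- nrow(P)
  vel <- matrix(0, n, 3L)
  labels <- integer(n)
  for (p in seq_along(spec@pipes)) {
    pipe <- spec@pipes[[p]]
    rel <- sweep(P, 2L, pipe@center)
    proj <- as.numeric(rel %*% pipe@axis)
    d2 <- pmax(rowSums(rel^2) - proj^2, 0)
    inside <- d2 <= pipe@radius^2
    if (any(labels[inside] != 0L))
      stop("pipes overlap on the grid; adjust the phantom geometry")
    labels[inside] <- p
    speed <- pipe@peakSpeed * exp(-d2[inside] / (2 * pipe@profileSigma^2))
    vel[inside, ] <- vel[inside, ] + outer(speed, pipe@axis)
  }
  s <- grid@shape
  varr <- array(vel, dim = c(s, 1L, 3L))
  list(truth = new("CineVelocityVolume", values = varr, grid = grid,
                   phases = 0),
       labels = array(labels, dim = s))
}

#' Magnitude cine volume of a phantom
#'
#' A synthetic anatomical counterpart used for masking: unit background with
#' bright (flowing blood) pipes, constant across cardiac frames.
#'
#' @param spec a [PhantomSpec-class].
#' @param labels pipe label array from [buildPhantom()] (recomputed if
#'   missing).
#' @param nPhases number of (identical) cardiac frames.
#' @param pipeIntensity magnitude inside pipes (background is 1).
#' @return a [CineMagnitudeVolume-class].
#' @export
phantomMagnitude <- function(spec, labels = NULL, nPhases = 1L,
                             pipeIntensity = 2) {
  if (is.null(labels)) labels <- buildPhantom(spec)$labels
  vol <- array(1, dim = dim(labels))
  vol[labels > 0L] <- pipeIntensity
  phases <- seq(0, 2 * pi, length.out = nPhases + 1L)[seq_len(nPhases)]
  new("CineMagnitudeVolume",
      values = array(rep(vol, nPhases), dim = c(dim(labels), nPhases)),
      grid = spec@grid, phases = phases)
}

#' Simulate a stack of velocity-sensitive phase images
#'
#' For every slice voxel the ground-truth velocity is sampled by trilinear
#' interpolation at the voxel's world center (after the frame's rigid
#' transform) and the bSSFP phase is formed as
#' wrap(s_world . v + N(0, noiseSigma^2)), where s_world is the stack
#' sensitivity rotated by the frame transform.  Magnitude is 1 inside the
#' phantom support (the ground-truth volume bounds) and 0 outside.  Slices
#' falling outside the truth volume yield zero-velocity background samples.
#' Identical seeds give bit-identical stacks.
#'
#' Frames are emitted with their sensitivity still tagged \code{"stack"}
#' (the as-prescribed static vector); apply [correctGradientMoments()]
#' before reconstruction.
#'
#' @param truth ground-truth [CineVelocityVolume-class].
#' @param stackGrid the stack's [VoxelGrid-class] (one frame per slice along
#'   the third axis); may be arbitrarily oriented relative to the truth grid.
#' @param sensitivity the stack's static [EncodingSensitivity-class]
#'   (frame \code{"stack"}).
#' @param noiseSigma phase noise standard deviation, rad.
#' @param seed integer RNG seed.
#' @param frameTransforms optional list of per-frame
#'   [RigidTransform-class] objects (motion injection); default identity.
#' @param framePhases optional per-frame cardiac phases in [0, 2*pi); the
#'   truth frame nearest in wrapped phase distance is sampled. Default 0.
#' @param frameTimes optional per-frame acquisition times, s.
#' @return a [FrameStack-class].
#' @export
simulateStack <- function(truth, stackGrid, sensitivity, noiseSigma = 0.10,
                          seed = 1L, frameTransforms = NULL,
                          framePhases = NULL, frameTimes = NULL) {
  s <- stackGrid@shape
  nSlices <- s[3]
  if (is.null(frameTransforms))
    frameTransforms <- rep(list(identityTransform()), nSlices)
  if (is.null(framePhases)) framePhases <- rep(0, nSlices)
  if (is.null(frameTimes)) frameTimes <- (seq_len(nSlices) - 1) * 0.072
  stopifnot(length(frameTransforms) == nSlices,
            length(framePhases) == nSlices)
  n1 <- s[1]; n2 <- s[2]
  pix <- cbind(rep.int(seq_len(n1) - 1L, n2),
               rep(seq_len(n2) - 1L, each = n1))
  varr <- truth@values
  tgrid <- truth@grid
  frames <- .withSeed(seed, {
    lapply(seq_len(nSlices), function(iz) {
      A <- frameTransforms[[iz]]
      sliceGrid <- .sliceGrid(stackGrid, iz - 1L)
      p0 <- worldCoords(sliceGrid, cbind(pix, 0))
      p <- applyTransform(A, p0)
      idx <- indexCoords(tgrid, p)
      h <- which.min(.wrappedDistance(truth@phases, framePhases[iz]))
      smp <- .trilinearVelocity(varr, idx, h = h)
      sW <- rotateSensitivity(sensitivity, A)
      phi <- as.numeric(smp$v %*% sW@s)
      if (noiseSigma > 0) phi <- phi + stats::rnorm(length(phi), 0, noiseSigma)
      new("FrameSample",
          phase = matrix(wrapPhase(phi), n1, n2),
          magnitude = matrix(as.numeric(smp$inside), n1, n2),
          grid2d = sliceGrid,
          transform = A,
          sensitivity = sensitivity,
          tAcq = frameTimes[iz],
          cardiacPhase = framePhases[iz] %% (2 * pi),
          frameWeight = 1)
    })
  })
  new("FrameStack", frames = frames, stackGrid = stackGrid)
}

# Geometry of slice `iz` (0-based) of a stack grid, as a 2D VoxelGrid.
.sliceGrid <- function(stackGrid, iz) {
  aff <- stackGrid@affine
  origin <- aff[1:3, 4] + aff[1:3, 3] * iz
  aff2 <- aff
  aff2[1:3, 4] <- origin
  new("VoxelGrid", shape = c(stackGrid@shape[1:2], 1L),
      spacing = stackGrid@spacing, affine = aff2)
}

#' Default five-stack acquisition plan
#'
#' The stack geometries and sensitivities of the simulated phantom study:
#' three axis-aligned stacks, each with slices orthogonal to one pipe pair,
#' plus two oblique stacks obtained by rotating axis-aligned geometries by
#' 45 degrees about z and about x.  Every stack carries the same
#' slice-frame sensitivity, oriented in the read/slice plane at
#' \code{encodingAngleDeg} from the slice normal, with the given VENC;
#' expressed in world coordinates the five directions span rank 3.
#'
#' @param spec a [PhantomSpec-class]; stack grids copy its shape/spacing.
#' @param venc velocity-encoding limit, cm/s.
#' @param encodingAngleDeg angle of the net first moment between slice
#'   normal and read axis, degrees.
#' @return list of 5 plans, each with elements \code{name}, \code{grid}
#'   (a [VoxelGrid-class]) and \code{sensitivity} (stack-tagged, expressed
#'   in world coordinates of the unmoved stack).
#' @export
defaultStackPlan <- function(spec, venc = 159, encodingAngleDeg = 45) {
  shape <- spec@grid@shape
  spacing <- spec@grid@spacing
  # Local slice axes are (read, phase-encode, slice-normal); the three
  # axis-aligned stacks use cyclically permuted world axes so that their
  # read/slice-plane sensitivities (x+y, y+z, z+x)/sqrt(2) sample the three
  # velocity components evenly.  Two oblique stacks rotate axis-aligned
  # geometries by 45 degrees about z and about x.
  Rx <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3L)  # slices along world x
  Ry <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3L)  # slices along world y
  R <- list(
    xstack = Rx,
    ystack = Ry,
    zstack = diag(3),
    oblique_z = axisRotation("z", 45) %*% Ry,
    oblique_x = axisRotation("x", 45) %*% diag(3))
  a <- encodingAngleDeg * pi / 180
  sLocal <- c(sin(a), 0, cos(a))  # read/slice plane, oblique to both
  lapply(seq_along(R), function(i) {
    rot <- R[[i]]
    dirWorld <- as.numeric(rot %*% sLocal)
    half <- floor(shape / 2) * spacing
    list(name = names(R)[i],
         grid = voxelGrid(shape, spacing,
                          origin = -as.numeric(rot %*% half),
                          rotation = rot),
         sensitivity = sensitivityFromVenc(venc, dirWorld, frame = "stack"))
  })
}

#' Simulate the default five-stack phantom acquisition
#'
#' Convenience wrapper: renders the ground truth and simulates all stacks of
#' [defaultStackPlan()] with per-stack seeds derived from the phantom seed.
#'
#' @param spec a [PhantomSpec-class].
#' @param plan stack plan from [defaultStackPlan()].
#' @param frameTransforms optional list (one entry per stack) of per-frame
#'   transform lists, for motion experiments.
#' @return list with \code{truth}, \code{labels} and \code{stacks}
#'   (list of [FrameStack-class]).
#' @export
simulatePhantomAcquisition <- function(spec, plan = defaultStackPlan(spec),
                                       frameTransforms = NULL) {
  built <- buildPhantom(spec)
  stacks <- lapply(seq_along(plan), function(i) {
    simulateStack(built$truth, plan[[i]]$grid, plan[[i]]$sensitivity,
                  noiseSigma = spec@noiseSigma,
                  seed = spec@seed * 101L + i,
                  frameTransforms = if (is.null(frameTransforms)) NULL
                                    else frameTransforms[[i]])
  })
  list(truth = built$truth, labels = built$labels, stacks = stacks)
}
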