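# Shared fixtures for the test suite.  Everything is generated in code;
# expensive reconstructions are computed once per session and cached.

.cache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .cache))
    assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

# A small phantom (24^3 at 2 mm) that keeps unit tests fast.
smallPhantomSpec <- function(noiseSigma = 0, seed = 7L) {
  defaultPhantom(gridSize = 24, spacing = 2, noiseSigma = noiseSigma,
                 seed = seed, offset = 8, radius = 3)
}

smallPhantom <- function() {
  cachedFixture("smallPhantom", buildPhantom(smallPhantomSpec()))
}

# Three noiseless stacks coincident with the truth grid, orthogonal
# world-axis sensitivities; delta-PSF reconstruction of these matches the
# per-voxel least-squares oracle.
coincidentStacks <- function(truth, grid, venc = 159, noiseSigma = 0,
                             seed = 1L) {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  lapply(1:3, function(k)
    simulateStack(truth, grid,
                  sensitivityFromVenc(venc, dirs[k, ], frame = "stack"),
                  noiseSigma = noiseSigma, seed = seed + k))
}

# Independent brute-force oracle: per-voxel 3x3 weighted least squares
# from per-stack phase volumes sampled on the truth grid itself.
perVoxelWlsOracle <- function(stacks) {
  S <- t(sapply(stacks, function(st) st[[1]]@sensitivity@s))
  H <- crossprod(S)
  phiMat <- sapply(seq_along(stacks), function(k)
    unlist(lapply(frames(stacks[[k]]), function(f) as.numeric(f@phase))))
  t(solve(H, t(phiMat %*% S)))
}

# Random rigid rotation up to maxAngleDeg about a random axis.
randomRigid <- function(maxAngleDeg, maxShiftMm = 0) {
  ax <- stats::rnorm(3)
  rigidTransform(axisRotation(ax, stats::runif(1, -1, 1) * maxAngleDeg),
                 stats::runif(3, -1, 1) * maxShiftMm)
}
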