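test_that("acquisition times map to cardiac phases modulo the R-R interval", {
  timing <- cardiacTiming(c(sl1 = 0.45, sl2 = 0.5),
                          c(sl1 = 0.1, sl2 = 0))
  expect_equal(assignCardiacPhase(0.1, timing, "sl1"), 0)
  expect_equal(assignCardiacPhase(0.1 + 0.225, timing, "sl1"), pi)
  expect_equal(assignCardiacPhase(0.1 + 0.45, timing, "sl1"), 0)  # wraps
  expect_equal(assignCardiacPhase(1, timing, "sl2"),
               2 * pi * ((1 %% 0.5) / 0.5))
  expect_error(assignCardiacPhase(1, timing, "sl9"), "no cardiac timing")
})

test_that("spatial PSF weights normalize and follow the Gaussian profile", {
  g <- voxelGrid(c(11, 11, 11), 1, origin = c(-5, -5, -5))
  m0 <- weightModel(supportRadius = 0L)
  w0 <- spatialWeights(c(0, 0, 0), g, m0)
  expect_equal(nrow(w0), 1L)
  expect_equal(w0$weight, 1)
  expect_equal(c(w0$i, w0$j, w0$k), c(5, 5, 5))

  fwhm1 <- 2 * sqrt(2 * log(2))   # FWHM giving sigma exactly 1 mm
  m <- weightModel(psfFwhmInplane = fwhm1, psfFwhmThrough = fwhm1,
                   supportRadius = 2L, weightTrim = 0)
  set.seed(12)
  for (i in 1:20) {
    p <- runif(3, -2, 2)
    w <- spatialWeights(p, g, m)
    expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  }
  # isotropic sigma = 1 mm: voxel at distance 1 vs center voxel ratio
  wc <- spatialWeights(c(0, 0, 0), g, m)
  ctr <- wc$weight[wc$i == 5 & wc$j == 5 & wc$k == 5]
  nb <- wc$weight[wc$i == 6 & wc$j == 5 & wc$k == 5]
  expect_equal(nb / ctr, exp(-0.5), tolerance = 1e-10)

  # far outside the grid: empty support
  expect_equal(nrow(spatialWeights(c(100, 0, 0), g, m)), 0L)
})

test_that("temporal weights form a symmetric wrapped-Gaussian kernel", {
  m <- weightModel(temporalSigma = 0.4)
  expect_equal(temporalWeight(1.3, 1.3, m), 1)
  expect_equal(temporalWeight(1.3, 1.7, m), exp(-0.5))
  expect_equal(temporalWeight(0.1, 2 * pi - 0.1, m),
               exp(-0.2^2 / (2 * 0.4^2)))   # wraps across the cycle
  expect_equal(temporalWeight(0.3, 2.2, m), temporalWeight(2.2, 0.3, m))
})

test_that("phase prediction is linear and exact for constant fields", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  g <- spec@grid
  stacks <- correctGradientMoments(
    coincidentStacks(b$truth, g)[1:2])
  m0 <- weightModel(supportRadius = 0L)

  zero <- new("CineVelocityVolume",
              values = array(0, c(g@shape, 1, 3)), grid = g, phases = 0)
  predZ <- predictPhase(zero, stacks, m0)
  expect_true(all(unlist(predZ) == 0))

  # constant field on a coincident grid: phi = s . v0 everywhere
  v0 <- c(7, -3, 2)
  cst <- zero
  for (q in 1:3) cst@values[, , , 1, q] <- v0[q]
  pred <- predictPhase(cst, stacks, m0)
  s1 <- stacks[[1]][[1]]@sensitivity@s
  expect_lt(max(abs(pred[[1]] - sum(s1 * v0))), 1e-12)

  # with the full PSF, weights sum to one so constants are still exact
  predPsf <- predictPhase(cst, stacks, weightModel())
  inside <- !is.na(predPsf[[5]])
  expect_lt(max(abs(predPsf[[5]][inside] - sum(s1 * v0))), 1e-10)

  # linearity of the operator
  set.seed(31)
  u <- zero; w <- zero
  u@values[] <- rnorm(length(u@values), sd = 3)
  w@values[] <- rnorm(length(w@values), sd = 3)
  a <- 1.7; bco <- -0.6
  lin <- u; lin@values <- a * u@values + bco * w@values
  pl <- predictPhase(lin, stacks, m0)
  pu <- predictPhase(u, stacks, m0)
  pw <- predictPhase(w, stacks, m0)
  expect_lt(max(abs(pl[[1]] - (a * pu[[1]] + bco * pw[[1]]))), 1e-10)

  # stack-frame sensitivities are rejected
  raw <- coincidentStacks(b$truth, g)[1:2]
  expect_error(predictPhase(cst, raw, m0), "stack-frame")
})

test_that("residuals weight frames by their outlier weight", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  stacks <- correctGradientMoments(coincidentStacks(b$truth, spec@grid)[1])
  m0 <- weightModel(supportRadius = 0L)
  pred <- predictPhase(b$truth, stacks, m0)
  res <- phaseResiduals(stacks, pred)
  expect_equal(res$sse, 0, tolerance = 1e-18)

  # a single 0.2 rad error with unit weight contributes 0.04
  pred2 <- pred
  pred2[[1]][3, 3] <- pred2[[1]][3, 3] + 0.2
  expect_equal(phaseResiduals(stacks, pred2)$sse, 0.04, tolerance = 1e-12)

  # zero-weight frames contribute nothing to the SSE
  st <- stacks[[1]]
  st@frames[[1]]@frameWeight <- 0
  stacksW <- list(st)
  predW <- pred
  predW[[1]][] <- 0   # corrupt the prediction of the zero-weight frame
  expect_equal(phaseResiduals(stacksW, predW)$sse,
               phaseResiduals(stacksW, pred)$sse)
})

test_that("regularizer value and analytic gradient are correct", {
  # constant field: zero value and gradient
  cst <- array(3.3, dim = c(4, 5, 3, 1, 3))
  r0 <- velocityRegularizer(cst, delta = 5)
  expect_equal(r0$value, 0)
  expect_true(all(r0$gradient == 0))

  # a single pair difference of delta contributes rho(1) = 2 (sqrt(2) - 1)
  a <- array(0, dim = c(2, 1, 1, 1, 1))
  a[2, 1, 1, 1, 1] <- 5
  r1 <- velocityRegularizer(a, delta = 5)
  expect_equal(r1$value, 2 * (sqrt(2) - 1), tolerance = 1e-12)

  # finite-difference gradient check on random small fields
  set.seed(55)
  for (rep in 1:5) {
    v <- array(rnorm(4 * 4 * 4 * 1 * 3, sd = 8), dim = c(4, 4, 4, 1, 3))
    rg <- velocityRegularizer(v, delta = 5)
    h <- 1e-5
    for (probe in 1:10) {
      i <- sample(length(v), 1)
      vp <- v; vp[i] <- vp[i] + h
      vm <- v; vm[i] <- vm[i] - h
      fd <- (velocityRegularizer(vp, 5, gradient = FALSE)$value -
               velocityRegularizer(vm, 5, gradient = FALSE)$value) / (2 * h)
      expect_equal(rg$gradient[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("reconstruction solves trivial and oracle problems", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  g <- spec@grid
  m0 <- weightModel(supportRadius = 0L)
  cfg <- reconConfig(lambda = 0, maxIter = 60, gradTol = 1e-14)

  # all phases zero: the zero volume is the global minimum
  zeroTruth <- b$truth
  zeroTruth@values[] <- 0
  stacks0 <- correctGradientMoments(coincidentStacks(zeroTruth, g))
  rec0 <- reconstructVelocity(stacks0, g, model = m0, config = cfg)
  expect_true(all(rec0@volume@values == 0))

  # noiseless coincident-grid stacks match the per-voxel WLS oracle
  stacks <- correctGradientMoments(coincidentStacks(b$truth, g))
  rec <- reconstructVelocity(stacks, g, model = m0, config = cfg)
  oracle <- perVoxelWlsOracle(stacks)
  expect_lt(max(abs(matrix(rec@volume@values, ncol = 3) - oracle)), 1e-6)

  # the objective never increases
  expect_true(all(diff(rec@objective) <= 1e-9))

  # degenerate inputs error out
  expect_error(reconstructVelocity(list(), g), "no frames")
  stZ <- stacks[[1]]
  stZ@frames <- lapply(stZ@frames, function(f) { f@frameWeight <- 0; f })
  expect_error(reconstructVelocity(list(stZ), g), "zero")
})

test_that("coverage map flags under-encoded voxels", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  g <- spec@grid
  m0 <- weightModel(supportRadius = 0L)
  stacks <- correctGradientMoments(coincidentStacks(b$truth, g))

  # a single stack gives rank 1 everywhere
  cov1 <- coverageMap(stacks[1], g, m0)
  expect_true(all(cov1$rank[cov1$sampled] == 1L))
  expect_true(all(cov1$flagged))

  # two stacks: rank 2, still flagged
  cov2 <- coverageMap(stacks[1:2], g, m0)
  expect_true(all(cov2$rank[cov2$sampled] == 2L))

  # all three orthogonal stacks: rank 3, condition 1, unflagged
  cov3 <- coverageMap(stacks, g, m0)
  expect_true(all(cov3$rank[cov3$sampled] == 3L))
  expect_true(all(!cov3$flagged[cov3$sampled]))

  # eigenvalue path agrees with base eigen() on random encodings
  set.seed(66)
  for (i in 1:50) {
    A <- crossprod(matrix(rnorm(9), 3))
    ev <- cineflow:::.sym3Eigenvalues(A[1, 1], A[2, 2], A[3, 3],
                                      A[1, 2], A[1, 3], A[2, 3])
    expect_equal(as.numeric(ev), eigen(A, symmetric = TRUE)$values,
                 tolerance = 1e-9)
  }
})

test_that("cine reconstruction resolves phase-dependent flow", {
  # tiny pulsatile phantom: velocity scales with the cardiac phase
  g <- voxelGrid(c(10, 10, 10), 2, origin = c(-9, -9, -9))
  nh <- 2L
  phases <- c(0, pi)
  varr <- array(0, dim = c(10, 10, 10, nh, 3))
  core <- as.matrix(expand.grid(4:7, 4:7, 1:10))
  for (h in 1:nh) {
    amp <- c(20, 40)[h]
    varr[, , , h, 3][core] <- amp
  }
  truth <- new("CineVelocityVolume", values = varr, grid = g,
               phases = phases)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  stacks <- list()
  for (h in 1:nh) for (k in 1:3) {
    st <- simulateStack(truth, g,
                        sensitivityFromVenc(159, dirs[k, ], "stack"),
                        noiseSigma = 0, seed = 10 * h + k,
                        framePhases = rep(phases[h], 10))
    stacks <- c(stacks, list(st))
  }
  stacks <- correctGradientMoments(stacks)
  rec <- reconstructVelocity(stacks, g, phases = phases,
                             model = weightModel(supportRadius = 0L,
                                                 temporalSigma = 0.5),
                             config = reconConfig(lambda = 0,
                                                  maxIter = 80,
                                                  gradTol = 1e-12))
  v <- rec@volume@values
  expect_equal(median(v[, , , 1, 3][core]), 20, tolerance = 0.05)
  expect_equal(median(v[, , , 2, 3][core]), 40, tolerance = 0.05)
  expect_lt(max(abs(v[, , , 1, 1:2])), 0.5)
})
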