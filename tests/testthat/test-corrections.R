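# independent brute-force oracle: weighted normal equations over the raw
# (uncentered) monomial basis, solved directly
normalEquationsPoly3 <- function(points, values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(points))
  ex <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  ex <- ex[ex$a + ex$b + ex$c <= 3, ]
  X <- sapply(seq_len(nrow(ex)), function(j)
    points[, 1]^ex$a[j] * points[, 2]^ex$b[j] * points[, 3]^ex$c[j])
  XtW <- t(X * weights)
  beta <- solve(XtW %*% X, XtW %*% values)
  function(p) as.numeric(sapply(seq_len(nrow(ex)), function(j)
    p[, 1]^ex$a[j] * p[, 2]^ex$b[j] * p[, 3]^ex$c[j]) %*% beta)
}

randomPoly3Values <- function(points, coef) {
  ex <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  ex <- ex[ex$a + ex$b + ex$c <= 3, ]
  as.numeric(sapply(seq_len(nrow(ex)), function(j)
    points[, 1]^ex$a[j] * points[, 2]^ex$b[j] * points[, 3]^ex$c[j]) %*%
      coef)
}

test_that("third-order polynomial fits recover degree-3 fields exactly", {
  set.seed(101)
  pts <- matrix(runif(600, -30, 30), ncol = 3)

  # constant field
  fit <- fitPoly3(pts, rep(2.5, nrow(pts)))
  expect_lt(max(abs(evalPoly3(fit, pts) - 2.5)), 1e-10)

  # random degree-3 polynomial, noiseless: exact recovery on a fresh grid
  coef <- rnorm(20, sd = 0.01)
  vals <- randomPoly3Values(pts, coef)
  fit <- fitPoly3(pts, vals)
  eva <- matrix(runif(300, -30, 30), ncol = 3)
  expect_lt(max(abs(evalPoly3(fit, eva) - randomPoly3Values(eva, coef))),
            1e-8)

  # underdetermined and degenerate designs fail loudly
  expect_error(fitPoly3(pts[1:10, ], vals[1:10]), "at least 20")
  flat <- cbind(runif(40, -10, 10), runif(40, -10, 10), 0)  # coplanar
  expect_error(fitPoly3(flat, rnorm(40)), "rank-deficient")
})

test_that("weighted fits match the brute-force normal-equations oracle", {
  set.seed(202)
  for (rep in 1:50) {
    pts <- matrix(runif(40 * 3, -15, 15), ncol = 3)
    vals <- rnorm(40, sd = 2)
    wts <- runif(40, 0.1, 2)
    fit <- fitPoly3(pts, vals, wts)
    oracle <- normalEquationsPoly3(pts, vals, wts)
    eva <- matrix(runif(30, -12, 12), ncol = 3)
    expect_lt(max(abs(evalPoly3(fit, eva) - oracle(eva))), 1e-8)
  }
})

test_that("background correction removes injected polynomial phase", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  plan <- defaultStackPlan(spec)
  st <- simulateStack(b$truth, plan[[3]]$grid, plan[[3]]$sensitivity,
                      noiseSigma = 0, seed = 1)
  # inject a smooth degree-3 background into every frame
  poly <- function(p) 0.3 + 0.004 * p[, 1] - 0.003 * p[, 2] +
    1e-4 * p[, 1] * p[, 3] + 2e-6 * p[, 2]^3
  stBg <- st
  pix <- cbind(rep.int(0:23, 24), rep(0:23, each = 24), 0)
  for (k in seq_len(length(st))) {
    p <- worldCoords(st[[k]]@grid2d, pix)
    stBg@frames[[k]]@phase <-
      matrix(wrapPhase(as.numeric(st[[k]]@phase) + poly(p)), 24, 24)
  }
  labels <- b$labels
  mag <- phantomMagnitude(spec, labels)
  nb <- nonbloodMask(mag)          # background excluding all pipes

  corr <- backgroundCorrectStack(stBg, nb)
  for (k in c(1, 12, 24)) {
    e <- as.numeric(corr[[k]]@phase) - as.numeric(st[[k]]@phase)
    expect_lt(max(abs(wrapPhase(e))), 1e-6)
  }

  # the localized flow ("vessel") phase is preserved, background is flat
  full <- volumeMask(array(TRUE, dim = spec@grid@shape), spec@grid)
  stOnlyBg <- st
  for (k in seq_len(length(st))) {
    p <- worldCoords(st[[k]]@grid2d, pix)
    stOnlyBg@frames[[k]]@phase <- matrix(wrapPhase(poly(p)), 24, 24)
  }
  corrBg <- backgroundCorrectStack(stOnlyBg, full)
  expect_lt(max(abs(as.numeric(corrBg[[10]]@phase))), 1e-6)

  # empty mask errors
  empty <- volumeMask(array(FALSE, dim = spec@grid@shape), spec@grid)
  expect_error(backgroundCorrectStack(stBg, empty), "no stack voxels")

  # idempotence: correcting a corrected stack changes nothing (< 1e-6 rad)
  corr2 <- backgroundCorrectStack(corr, nb)
  expect_lt(max(abs(wrapPhase(as.numeric(corr2[[12]]@phase) -
                                as.numeric(corr[[12]]@phase)))), 1e-6)

  # geometry, sensitivity, transform and weights are untouched
  expect_identical(corr[[3]]@grid2d@affine, st[[3]]@grid2d@affine)
  expect_identical(corr[[3]]@sensitivity@s, st[[3]]@sensitivity@s)
  expect_identical(corr[[3]]@frameWeight, st[[3]]@frameWeight)
})

test_that("non-blood mask keeps only voxels dark in every frame", {
  g <- voxelGrid(c(6, 6, 6), 1)
  # constant zero magnitude: everything is non-blood
  x0 <- new("CineMagnitudeVolume", values = array(0, c(6, 6, 6, 3)),
            grid = g, phases = c(0, 2, 4))
  expect_true(all(values(nonbloodMask(x0))))

  # voxels bright in exactly one frame are excluded
  arr <- array(1, c(6, 6, 6, 3))
  arr[3:4, 3:4, 3:4, 2] <- 10   # blood passes through in frame 2 only
  x1 <- new("CineMagnitudeVolume", values = arr, grid = g,
            phases = c(0, 2, 4))
  m <- values(nonbloodMask(x1))
  expect_true(all(!m[3:4, 3:4, 3:4]))
  expect_true(all(m[1:2, , ]))

  expect_error(nonbloodMask(x1, thresholdFraction = 1.2), "between 0 and 1")

  # phantom: bright pipes are excluded, background retained
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  mag <- phantomMagnitude(spec, b$labels)
  m2 <- values(nonbloodMask(mag))
  expect_identical(m2, b$labels == 0L)
})

test_that("velocity drift correction removes smooth per-component drift", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  truth <- b$truth
  nb <- nonbloodMask(phantomMagnitude(spec, b$labels))
  centers <- voxelCenters(spec@grid)

  # constant offset: removed everywhere (degree 0 is inside the model)
  vOff <- truth
  for (q in 1:3) vOff@values[, , , 1, q] <-
    vOff@values[, , , 1, q] + c(3, -2, 1)[q]
  corr <- velocityDriftCorrect(vOff, nb)
  bg <- b$labels == 0L
  for (q in 1:3)
    expect_lt(max(abs(corr@values[, , , 1, q][bg] -
                        truth@values[, , , 1, q][bg])), 1e-6)

  # full degree-3 drift: removed over the whole volume, including pipes
  # (the correction subtracts the fitted field globally)
  drift <- list(
    function(p) 0.5 + 0.02 * p[, 1] + 1e-4 * p[, 2] * p[, 3],
    function(p) -1 + 1e-5 * p[, 1]^3,
    function(p) 0.01 * p[, 3] - 2e-4 * p[, 1] * p[, 2])
  vDr <- truth
  for (q in 1:3) vDr@values[, , , 1, q] <- vDr@values[, , , 1, q] +
    array(drift[[q]](centers), dim = spec@grid@shape)
  corr2 <- velocityDriftCorrect(vDr, nb)
  for (q in 1:3)
    expect_lt(max(abs(corr2@values[, , , 1, q] -
                        truth@values[, , , 1, q])), 1e-6)

  # residual background median vanishes
  med <- median(corr2@values[, , , 1, 1][bg])
  expect_lt(abs(med), 1e-6)

  empty <- volumeMask(array(FALSE, dim = spec@grid@shape), spec@grid)
  expect_error(velocityDriftCorrect(truth, empty), "empty")
})
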