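test_that("pipe profile is a truncated Gaussian", {
  p <- pipeSpec(c(0, 0, 1), c(0, 0, 0), radius = 5, peakSpeed = 80)
  expect_equal(pipeProfile(0, p), 80)
  expect_equal(pipeProfile(5 + 1e-9, p), 0)   # hard wall at the radius
  expect_equal(pipeProfile(p@profileSigma, p), 80 * exp(-0.5))
  expect_error(pipeProfile(-1, p), ">= 0")
})

test_that("ground-truth phantom has antiparallel pairs and zero background", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  peaks <- vapply(spec@pipes, function(p) p@peakSpeed, numeric(1))
  # six pipes in three antiparallel pairs at the nominal speeds
  expect_length(spec@pipes, 6L)
  expect_setequal(peaks, c(100, -100, 80, -80, 25, -25))
  sp <- sqrt(apply(b$truth@values[, , , 1, ]^2, 1:3, sum))
  expect_equal(max(sp[b$labels == 1]), 100)   # on-axis voxel hit exactly
  expect_equal(max(sp), 100)
  expect_true(all(sp[b$labels == 0] == 0))

  # paired pipes: equal-magnitude, opposite-sign flow along the shared axis
  for (pair in list(c(1L, 2L), c(3L, 4L), c(5L, 6L))) {
    a1 <- spec@pipes[[pair[1]]]@axis
    vmax1 <- max(abs(b$truth@values[, , , 1, which(a1 != 0)]
                     [b$labels == pair[1]]))
    vmax2 <- max(abs(b$truth@values[, , , 1, which(a1 != 0)]
                     [b$labels == pair[2]]))
    expect_equal(vmax1, vmax2)
    s1 <- sign(spec@pipes[[pair[1]]]@peakSpeed)
    s2 <- sign(spec@pipes[[pair[2]]]@peakSpeed)
    expect_equal(s1, -s2)
  }

  # overlapping pipes are rejected
  bad <- spec
  bad@pipes[[2]] <- spec@pipes[[1]]
  expect_error(buildPhantom(bad), "overlap")
})

test_that("truth field conserves axial flux between cross-sections", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  # pipe 1 flows along +x: discrete flux through interior yz-planes
  vx <- b$truth@values[, , , 1, 1]
  flux <- sapply(4:20, function(ix) sum(vx[ix, , ][b$labels[ix, , ] == 1L]))
  expect_lt(diff(range(flux)) / mean(flux), 0.005)
})

test_that("noiseless simulation matches the analytic forward model", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  plan <- defaultStackPlan(spec)

  # coincident grid: equality to machine precision (no interpolation)
  s <- sensitivityFromVenc(159, c(1, 0, 1) / sqrt(2), frame = "stack")
  st <- simulateStack(b$truth, spec@grid, s, noiseSigma = 0, seed = 1)
  fr <- st[[12]]
  pix <- cbind(rep.int(0:23, 24), rep(0:23, each = 24), 0)
  v <- b$truth@values[, , 12, 1, ]
  dim(v) <- c(24 * 24, 3)
  expected <- wrapPhase(as.numeric(v %*% s@s))
  expect_lt(max(abs(as.numeric(fr@phase) - expected)), 1e-12)

  # a sample voxel centered in a pipe reproduces the analytic profile phase
  axPlan <- plan[[1]]   # axis-aligned: samples fall on truth voxel centers
  stAx <- simulateStack(b$truth, axPlan$grid, axPlan$sensitivity,
                        noiseSigma = 0, seed = 1)
  # locate the sample at world (0, 8, 0): on the +100 pipe axis
  found <- FALSE
  for (k in seq_len(length(stAx))) {
    fr2 <- stAx[[k]]
    pw <- worldCoords(fr2@grid2d, pix)
    hit <- which(abs(pw[, 1]) < 1e-9 & abs(pw[, 2] - 8) < 1e-9 &
                   abs(pw[, 3]) < 1e-9)
    if (length(hit)) {
      sW <- rotateSensitivity(axPlan$sensitivity, fr2@transform)
      expect_lt(abs(as.numeric(fr2@phase)[hit] -
                      wrapPhase(sum(c(100, 0, 0) * sW@s))), 1e-3)
      found <- TRUE
    }
  }
  expect_true(found)

  # oblique stack agrees with an independent 8-corner trilinear oracle
  ob <- plan[[4]]
  stOb <- simulateStack(b$truth, ob$grid, ob$sensitivity,
                        noiseSigma = 0, seed = 1)
  frOb <- stOb[[12]]
  p <- applyTransform(frOb@transform, worldCoords(frOb@grid2d, pix))
  idx <- indexCoords(spec@grid, p)
  refTrilinear <- function(arr, ix) {
    d <- dim(arr)
    out <- numeric(nrow(ix))
    for (n in seq_len(nrow(ix))) {
      if (any(ix[n, ] < 0) || any(ix[n, ] > d - 1)) { out[n] <- 0; next }
      i0 <- pmin(floor(ix[n, ]), d - 2); f <- ix[n, ] - i0
      acc <- 0
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        w <- prod(ifelse(c(cx, cy, cz) == 1, f, 1 - f))
        acc <- acc + w * arr[i0[1] + cx + 1, i0[2] + cy + 1, i0[3] + cz + 1]
      }
      out[n] <- acc
    }
    out
  }
  vRef <- sapply(1:3, function(q)
    refTrilinear(b$truth@values[, , , 1, q], idx))
  sW <- rotateSensitivity(ob$sensitivity, frOb@transform)
  expect_lt(max(abs(as.numeric(frOb@phase) -
                      wrapPhase(as.numeric(vRef %*% sW@s)))), 1e-10)

  # slices beyond the truth volume give zero-velocity background
  far <- voxelGrid(c(8, 8, 1), 2, origin = c(500, 500, 500))
  stFar <- simulateStack(b$truth, far, s, noiseSigma = 0, seed = 1)
  expect_true(all(stFar[[1]]@phase == 0))
  expect_true(all(stFar[[1]]@magnitude == 0))
})

test_that("simulation is deterministic given a seed", {
  spec <- smallPhantomSpec()
  b <- smallPhantom()
  plan <- defaultStackPlan(spec)
  a <- simulateStack(b$truth, plan[[1]]$grid, plan[[1]]$sensitivity,
                     noiseSigma = 0.1, seed = 42)
  bb <- simulateStack(b$truth, plan[[1]]$grid, plan[[1]]$sensitivity,
                      noiseSigma = 0.1, seed = 42)
  cc <- simulateStack(b$truth, plan[[1]]$grid, plan[[1]]$sensitivity,
                      noiseSigma = 0.1, seed = 43)
  expect_identical(a[[5]]@phase, bb[[5]]@phase)
  expect_false(identical(a[[5]]@phase, cc[[5]]@phase))
})

test_that("default acquisition plan has five stacks spanning rank 3", {
  spec <- smallPhantomSpec()
  plan <- defaultStackPlan(spec)
  expect_length(plan, 5L)
  dirs <- t(sapply(plan, function(p) p$sensitivity@s))
  expect_equal(qr(dirs)$rank, 3L)
  expect_gt(svd(dirs)$d[3] / svd(dirs)$d[1], 0.1)  # usably conditioned
  for (p in plan) expect_equal(venc(p$sensitivity), 159, tolerance = 1e-12)
  # three axis-aligned stacks, each with slices orthogonal to one pipe pair
  normals <- t(sapply(plan[1:3], function(p) p$grid@affine[1:3, 3]))
  expect_equal(abs(normals) / spec@grid@spacing[3], diag(3)[c(1, 2, 3), ],
               tolerance = 1e-12, ignore_attr = TRUE)
})
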