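# Vectorized trilinear interpolation on 0-based fractional voxel indices.
# Points outside [0, dim-1] (to 1e-9) yield `outside`.
.trilinear <- function(arr, idx, outside = NA_real_) {
  d <- dim(arr)
  n <- nrow(idx)
  eps <- 1e-9
  inside <- idx[, 1] >= -eps & idx[, 1] <= d[1] - 1 + eps &
            idx[, 2] >= -eps & idx[, 2] <= d[2] - 1 + eps &
            idx[, 3] >= -eps & idx[, 3] <= d[3] - 1 + eps
  out <- rep(outside, n)
  if (!any(inside)) return(out)
  p <- idx[inside, , drop = FALSE]
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  p[, 3] <- pmin(pmax(p[, 3], 0), d[3] - 1)
  i0 <- floor(p)
  f <- p - i0
  # clamp the upper corner so boundary points index validly (weight 0 there)
  i1 <- sweep(i0 + 1, 2L, d[1:3] - 1, pmin)
  acc <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    ix <- if (cx) i1[, 1] else i0[, 1]
    iy <- if (cy) i1[, 2] else i0[, 2]
    iz <- if (cz) i1[, 3] else i0[, 3]
    lin <- 1 + ix + d[1] * (iy + d[2] * iz)
    acc <- acc + w * arr[lin]
  }
  out[inside] <- acc
  out
}

# Sample all three components of one cardiac frame of a velocity array
# (dim nx,ny,nz,Nh,3) at fractional indices; rows outside get zeros and
# inside=FALSE.
.trilinearVelocity <- function(varr, idx, h = 1L) {
  d <- dim(varr)
  nvox <- prod(d[1:3])
  out <- matrix(0, nrow(idx), 3L)
  ok <- logical(nrow(idx))
  for (q in 1:3) {
    comp <- varr[(1 + (h - 1L) * nvox + (q - 1L) * nvox * d[4]):
                 ((h - 1L) * nvox + (q - 1L) * nvox * d[4] + nvox)]
    dim(comp) <- d[1:3]
    v <- .trilinear(comp, idx)
    if (q == 1L) ok <- !is.na(v)
    v[is.na(v)] <- 0
    out[, q] <- v
  }
  list(v = out, inside = ok)
}
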