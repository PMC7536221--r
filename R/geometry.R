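#' Construct a voxel grid
#'
#' Builds a [VoxelGrid-class] from shape, spacing and either an explicit
#' affine or an origin plus rotation.  The affine maps 0-based voxel indices
#' (voxel centers) to world mm, RAS convention.
#'
#' @param shape integer(3) grid extents.
#' @param spacing numeric(3) or scalar voxel size in mm.
#' @param origin world position of the center of voxel (0,0,0), mm.
#'   Ignored when \code{affine} is given.
#' @param rotation 3x3 rotation matrix orienting the grid axes.
#'   Ignored when \code{affine} is given.
#' @param affine optional explicit 4x4 index-to-world affine.
#' @return a [VoxelGrid-class].
#' @examples
#' g <- voxelGrid(c(64, 64, 64), 1.25)
#' worldCoords(g, c(1, 0, 0))
#' @export
voxelGrid <- function(shape, spacing, origin = c(0, 0, 0),
                      rotation = diag(3), affine = NULL) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- rotation %*% diag(spacing)
    affine[1:3, 4] <- origin
  }
  new("VoxelGrid", shape = shape, spacing = spacing, affine = affine)
}

#' Grid centered on the world origin
#'
#' Convenience constructor for a grid whose center coincides with the world
#' origin after applying \code{rotation}.
#' @inheritParams voxelGrid
#' @return a [VoxelGrid-class].
#' @export
centeredGrid <- function(shape, spacing, rotation = diag(3)) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  half <- (shape - 1) / 2 * spacing
  voxelGrid(shape, spacing, origin = -as.numeric(rotation %*% half),
            rotation = rotation)
}

.asPointMatrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    p
  } else {
    stopifnot(length(p) == 3L)
    matrix(p, 1L, 3L)
  }
}

.maybeDrop <- function(m, wasVector) if (wasVector) m[1L, ] else m

#' Voxel indices to world coordinates
#'
#' Applies the grid affine to (fractional, 0-based) voxel indices.
#'
#' @param grid a [VoxelGrid-class].
#' @param index numeric(3) or an n x 3 matrix of fractional voxel indices.
#' @return world point(s) in mm, same shape as the input.
#' @seealso [indexCoords()] for the inverse mapping.
#' @export
worldCoords <- function(grid, index) {
  v <- !is.matrix(index)
  m <- .asPointMatrix(index)
  out <- m %*% t(grid@affine[1:3, 1:3])
  out <- sweep(out, 2L, grid@affine[1:3, 4], "+")
  .maybeDrop(out, v)
}

#' World coordinates to (fractional) voxel indices
#'
#' @param grid a [VoxelGrid-class].
#' @param point numeric(3) or an n x 3 matrix of world points in mm.
#' @return fractional 0-based voxel indices, same shape as the input.
#' @export
indexCoords <- function(grid, point) {
  v <- !is.matrix(point)
  m <- .asPointMatrix(point)
  inv <- solve(grid@affine[1:3, 1:3])
  out <- sweep(m, 2L, grid@affine[1:3, 4], "-") %*% t(inv)
  .maybeDrop(out, v)
}

#' World coordinates of every voxel center
#'
#' @param grid a [VoxelGrid-class].
#' @return an (prod(shape)) x 3 matrix in R array (column-major) voxel order.
#' @export
voxelCenters <- function(grid) {
  s <- grid@shape
  idx <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2]))
  worldCoords(grid, idx)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix, determinant +1.
#' @param translation numeric(3) in mm.
#' @return a [RigidTransform-class].
#' @examples
#' rigidTransform(axisRotation("z", 90), c(0, 0, 5))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Identity rigid transform
#' @return a [RigidTransform-class] with identity rotation, zero translation.
#' @export
identityTransform <- function() rigidTransform()

#' Rotation matrix about a coordinate axis or arbitrary axis
#'
#' @param axis \code{"x"}, \code{"y"}, \code{"z"}, or a 3-vector.
#' @param angleDeg rotation angle in degrees (right-handed).
#' @return a 3x3 rotation matrix.
#' @export
axisRotation <- function(axis, angleDeg) {
  th <- angleDeg * pi / 180
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to world points
#'
#' Computes R p + t.  Rigid transforms are isometries: pairwise distances
#' are preserved.
#'
#' @param transform a [RigidTransform-class].
#' @param point numeric(3) or n x 3 matrix of world points (mm).
#' @return transformed point(s), same shape as the input.
#' @export
applyTransform <- function(transform, point) {
  v <- !is.matrix(point)
  m <- .asPointMatrix(point)
  out <- m %*% t(transform@rotation)
  out <- sweep(out, 2L, transform@translation, "+")
  .maybeDrop(out, v)
}

#' Compose two rigid transforms
#'
#' Returns the transform applying \code{second} first, then \code{first},
#' i.e. \code{composeTransforms(a, b)(p) == a(b(p))}.
#'
#' @param first,second [RigidTransform-class] objects.
#' @return the composed [RigidTransform-class].
#' @export
composeTransforms <- function(first, second) {
  rigidTransform(first@rotation %*% second@rotation,
                 as.numeric(first@rotation %*% second@translation) +
                   first@translation)
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}
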