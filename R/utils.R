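# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 0-based voxel indices (n x 3) -> world mm (n x 3).
voxelToWorldMm <- function(idx, affine) {
  idx <- matrix(idx, ncol = 3)
  h <- cbind(idx, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

# world mm (n x 3) -> continuous 0-based voxel indices (n x 3).
worldToVoxelIdx <- function(mm, affine) {
  mm <- matrix(mm, ncol = 3)
  h <- cbind(mm, 1) %*% t(solve(affine))
  h[, 1:3, drop = FALSE]
}

# All 0-based voxel indices of a grid, as an N x 3 matrix (column-major order,
# matching as.vector() of an array of that shape).
gridIndices <- function(shape) {
  as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                        k = 0:(shape[3] - 1L), KEEP.OUT.ATTRS = FALSE))
}

# n x 3 matrix of 0-based indices -> 1-based linear indices.
linearIndex <- function(idx, shape) {
  1L + idx[, 1] + shape[1] * (idx[, 2] + shape[2] * idx[, 3])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Constructor shorthands used throughout the package and its tests.

#' Construct a LabelVolume
#' @param data 3-D array of non-negative integer labels (0 = background).
#' @param affine 4x4 voxel-to-world transform; default identity (1 mm voxels).
#' @return a [LabelVolume-class].
#' @export
labelVolume <- function(data, affine = diag(4)) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, affine = affine)
}

#' Construct a ScalarVolume
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world transform; default identity.
#' @return a [ScalarVolume-class].
#' @export
scalarVolume <- function(data, affine = diag(4)) {
  storage.mode(data) <- "double"
  new("ScalarVolume", data = data, affine = affine)
}

#' Construct an AffineTransform
#' @param matrix 4x4 invertible matrix (last row 0 0 0 1) mapping source-space
#'   mm coordinates to target-space mm coordinates.
#' @param sourceSpace,targetSpace names of the two spaces.
#' @return an [AffineTransform-class].
#' @export
affineTransform <- function(matrix = diag(4), sourceSpace = "source",
                            targetSpace = "target") {
  new("AffineTransform", matrix = matrix, sourceSpace = sourceSpace,
      targetSpace = targetSpace)
}
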