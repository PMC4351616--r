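#' Read a labeled NIfTI volume
#'
#' Reads a 3-D NIfTI image whose voxel values are integer labels (a
#' parcellation or a binary mask) and returns it with its world affine.
#' Voxel values further than 1e-6 from an integer are rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [LabelVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(labelVolume(array(0:1, c(4, 4, 4))), f)
#' readLabelVolume(f)
#' @export
readLabelVolume <- function(path) {
  img <- .readNifti3D(path)
  d <- as.array(img)
  off <- abs(d - round(d))
  if (any(off > 1e-6)) {
    bad <- d[which.max(off)]
    stopf("non-integer label value %g in %s", bad, path)
  }
  labelVolume(array(as.integer(round(d)), dim = dim(d)),
              affine = .xformMatrix(img))
}

#' Read a scalar NIfTI volume
#'
#' @param path path to a 3-D `.nii` / `.nii.gz` file of finite real values.
#' @return a [ScalarVolume-class].
#' @export
readScalarVolume <- function(path) {
  img <- .readNifti3D(path)
  d <- as.array(img)
  if (any(!is.finite(d)))
    stopf("non-finite voxel values in %s", path)
  scalarVolume(array(as.double(d), dim = dim(d)), affine = .xformMatrix(img))
}

.readNifti3D <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stopf("%s is %d-D; a 3-D volume is required", path, length(dim(img)))
  img
}

.xformMatrix <- function(img) {
  m <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  matrix(as.double(m), 4, 4)
}

#' Write a volume as NIfTI
#'
#' Label volumes are written as 32-bit integers, scalar volumes as 64-bit
#' floats; the affine is stored in the sform (and qform) fields.
#'
#' @param vol a [LabelVolume-class] or [ScalarVolume-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  dtype <- if (is(vol, "LabelVolume")) "int32" else "double"
  img <- RNifti::asNifti(vol@data, datatype = dtype)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4x4 affine transform from a text file
#'
#' The file holds four whitespace-delimited rows of four numbers (the plain
#' text matrix dialect used by linear registration tools: row-major,
#' source-space mm to target-space mm).
#'
#' @param path text file with the 4x4 matrix.
#' @param sourceSpace,targetSpace optional names for the two spaces.
#' @return an [AffineTransform-class].
#' @export
readAffineTransform <- function(path, sourceSpace = "source",
                                targetSpace = "target") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  vals <- scan(path, quiet = TRUE, comment.char = "#")
  if (length(vals) != 16L)
    stopf("%s does not hold a 4x4 matrix (found %d values)", path,
          length(vals))
  affineTransform(matrix(vals, 4, 4, byrow = TRUE), sourceSpace, targetSpace)
}

#' Write a 4x4 affine transform to a text file
#' @param xfm an [AffineTransform-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAffineTransform <- function(xfm, path) {
  stopifnot(is(xfm, "AffineTransform"))
  writeLines(apply(xfm@matrix, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "  ")), path)
  invisible(path)
}

# Map every target voxel index to its continuous source voxel index.
# Composition: target idx -> target mm -> (inverse world xfm) source mm ->
# source idx.  `xfm` maps source-space mm to target-space mm.
.sourceCoords <- function(srcAffine, xfmMatrix, targetShape, targetAffine) {
  if (abs(det(targetAffine)) < .Machine$double.eps * 64)
    stopf("singular target affine")
  M <- solve(srcAffine) %*% solve(xfmMatrix) %*% targetAffine
  idx <- gridIndices(targetShape)
  s <- cbind(idx, 1) %*% t(M)
  s[, 1:3, drop = FALSE]
}

#' Resample a label volume onto a target grid
#'
#' Nearest-neighbor resampling of an integer-labeled volume through a world
#' affine, the standard choice for categorical data: the output can never
#' contain a label absent from the input. Voxels mapping outside the source
#' field of view become background (0).
#'
#' @param vol a [LabelVolume-class] in the source space.
#' @param xfm an [AffineTransform-class] mapping source mm to target mm.
#' @param targetShape integer triple of the output grid.
#' @param targetAffine 4x4 voxel-to-world transform of the output grid.
#' @return a [LabelVolume-class] on the target grid.
#' @export
resampleLabels <- function(vol, xfm, targetShape, targetAffine) {
  stopifnot(is(vol, "LabelVolume"), is(xfm, "AffineTransform"))
  targetShape <- as.integer(targetShape)
  s <- round(.sourceCoords(vol@affine, xfm@matrix, targetShape, targetAffine))
  shp <- dim(vol@data)
  ok <- s[, 1] >= 0 & s[, 1] < shp[1] & s[, 2] >= 0 & s[, 2] < shp[2] &
    s[, 3] >= 0 & s[, 3] < shp[3]
  out <- integer(prod(targetShape))
  if (any(ok))
    out[ok] <- vol@data[linearIndex(s[ok, , drop = FALSE], shp)]
  labelVolume(array(out, dim = targetShape), affine = targetAffine)
}

#' Resample a scalar volume onto a target grid
#'
#' Trilinear interpolation through a world affine; output values are convex
#' combinations of input values (hence bounded by the input range), and
#' voxels mapping outside the source field of view become 0.
#'
#' @inheritParams resampleLabels
#' @param vol a [ScalarVolume-class] in the source space.
#' @return a [ScalarVolume-class] on the target grid.
#' @export
resampleScalar <- function(vol, xfm, targetShape, targetAffine) {
  stopifnot(is(vol, "ScalarVolume"), is(xfm, "AffineTransform"))
  targetShape <- as.integer(targetShape)
  s <- .sourceCoords(vol@affine, xfm@matrix, targetShape, targetAffine)
  out <- .trilinear(vol@data, s)
  scalarVolume(array(out, dim = targetShape), affine = targetAffine)
}

# Trilinear interpolation of array `a` at continuous 0-based coords (N x 3).
# Corners outside the grid contribute value 0 (out-of-field convention).
.trilinear <- function(a, s) {
  shp <- dim(a)
  f <- floor(s)
  w <- s - f
  out <- numeric(nrow(s))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- f[, 1] + dx; cj <- f[, 2] + dy; ck <- f[, 3] + dz
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    ok <- ci >= 0 & ci < shp[1] & cj >= 0 & cj < shp[2] &
      ck >= 0 & ck < shp[3] & wt > 0
    if (any(ok)) {
      lin <- 1L + ci[ok] + shp[1] * (cj[ok] + shp[2] * ck[ok])
      out[ok] <- out[ok] + wt[ok] * a[lin]
    }
  }
  out
}
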