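#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## Shared checks -------------------------------------------------------------

.checkAffine <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (any(!is.finite(m)))
    return("affine contains non-finite entries")
  if (abs(det(m)) < .Machine$double.eps * 64)
    return("affine is singular")
  if (any(abs(m[4, ] - c(0, 0, 0, 1)) > 1e-8))
    return("last affine row must be (0, 0, 0, 1)")
  NULL
}

.checkVolumeCore <- function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  aff <- .checkAffine(object@affine)
  if (!is.null(aff)) msg <- c(msg, aff)
  if (length(msg)) msg else NULL
}

## Core volume containers ----------------------------------------------------

#' BrainVolume: virtual parent of voxel-grid containers
#'
#' Holds a 3-D voxel array together with the 4x4 world affine mapping 0-based
#' voxel indices (i, j, k) to millimetre coordinates, following the NIfTI
#' (RAS+) convention.
#'
#' @slot data 3-D array of voxel values.
#' @slot affine 4x4 voxel-index-to-world (mm) transform.
#' @export
setClass("BrainVolume", representation("VIRTUAL",
  data = "array", affine = "matrix"))

#' LabelVolume: integer-labeled 3-D volume
#'
#' Stores a labeled parcellation or a binary mask: non-negative integer labels
#' on a 3-D lattice with its world affine. Label 0 is background.
#'
#' @slot data 3-D array of non-negative integers.
#' @slot affine 4x4 voxel-to-world transform (invertible, last row 0 0 0 1).
#' @seealso [readLabelVolume()], [resampleLabels()], [buildShell()]
#' @export
setClass("LabelVolume", contains = "BrainVolume")

setValidity("LabelVolume", function(object) {
  msg <- .checkVolumeCore(object)
  d <- object@data
  if (length(d) && (any(d < 0) || any(abs(d - round(d)) > 1e-6)))
    msg <- c(msg, "labels must be non-negative integers")
  if (is.null(msg)) TRUE else msg
})

#' ScalarVolume: real-valued 3-D volume
#'
#' Holds continuous voxel data (counts, connectivity values, statistical
#' maps). Values must be finite; `NA` is permitted only for masked-out voxels
#' produced by the statistics stage.
#'
#' @slot data 3-D numeric array.
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("ScalarVolume", contains = "BrainVolume")

setValidity("ScalarVolume", function(object) {
  msg <- .checkVolumeCore(object)
  d <- object@data
  if (length(d) && any(is.infinite(d) | is.nan(d)))
    msg <- c(msg, "scalar volume contains non-finite values")
  if (is.null(msg)) TRUE else msg
})

#' AffineTransform: a named 4x4 world-space transform
#'
#' A rigid/affine mapping between two named coordinate spaces, as produced by
#' linear registration tools. The matrix maps source-space world (mm)
#' coordinates to target-space world coordinates.
#'
#' @slot matrix 4x4 invertible matrix, last row (0, 0, 0, 1).
#' @slot sourceSpace,targetSpace character names of the two spaces.
#' @export
setClass("AffineTransform", representation(
  matrix = "matrix", sourceSpace = "character", targetSpace = "character"))

setValidity("AffineTransform", function(object) {
  msg <- .checkAffine(object@matrix)
  if (is.null(msg)) TRUE else msg
})

## Transition shell ----------------------------------------------------------

#' TransitionShell: the gray-white matter boundary layer
#'
#' The set of white-matter voxels having face contact (6-connectivity) with
#' gray matter, each assigned to one gray matter ROI by majority voting over
#' its up-to-six face neighbors. Voxel indices are 0-based.
#'
#' @slot voxels n x 3 integer matrix of 0-based (i, j, k) shell voxel indices.
#' @slot labels integer vector of assigned ROI labels, parallel to `voxels`.
#' @slot gridShape integer triple, the grid the shell lives on.
#' @slot affine 4x4 voxel-to-world transform of that grid.
#' @slot seed integer seed used for random tie-breaking during assignment.
#' @seealso [buildShell()], [shellToLabelVolume()]
#' @export
setClass("TransitionShell", representation(
  voxels = "matrix", labels = "integer", gridShape = "integer",
  affine = "matrix", seed = "integer"))

setValidity("TransitionShell", function(object) {
  msg <- character()
  v <- object@voxels
  if (ncol(v) != 3L) msg <- c(msg, "voxels must be an n x 3 matrix")
  if (nrow(v) != length(object@labels))
    msg <- c(msg, "labels must be parallel to voxels")
  if (length(object@labels) && any(object@labels <= 0L))
    msg <- c(msg, "assigned labels must be positive")
  if (nrow(v)) {
    if (any(v < 0) || any(sweep(v, 2, object@gridShape, ">=")))
      msg <- c(msg, "shell voxels outside grid")
    if (anyDuplicated(v))
      msg <- c(msg, "duplicate shell voxels")
  }
  aff <- .checkAffine(object@affine)
  if (!is.null(aff)) msg <- c(msg, aff)
  if (length(msg)) msg else TRUE
})

## Tractography --------------------------------------------------------------

#' TrackingParams: streamline propagation settings
#'
#' Parameters of the simplified probabilistic streamline propagator. Defaults
#' are the standard probabilistic-tractography settings: 5000 samples per seed
#' voxel, curvature threshold 0.2 (minimum cosine between successive step
#' directions), 200 maximum steps, 0.5 mm step length, distance correction on.
#'
#' @slot nSamples streamlines launched per seed voxel.
#' @slot curvatureThreshold minimum cosine between successive steps in [-1, 1].
#' @slot maxSteps maximum number of integration steps per streamline.
#' @slot stepLengthMm step length in millimetres.
#' @slot distanceCorrection weight visits by path length at first visit.
#' @slot dispersionDeg angular jitter (degrees, sd) of the direction sampler.
#' @slot bidirectional propagate both field polarities from each seed.
#' @slot seed integer RNG seed.
#' @seealso [trackingParams()], [seedRoiTracking()]
#' @export
setClass("TrackingParams", representation(
  nSamples = "integer", curvatureThreshold = "numeric", maxSteps = "integer",
  stepLengthMm = "numeric", distanceCorrection = "logical",
  dispersionDeg = "numeric", bidirectional = "logical", seed = "integer"))

setValidity("TrackingParams", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@stepLengthMm <= 0) msg <- c(msg, "stepLengthMm must be > 0")
  if (object@maxSteps < 1L) msg <- c(msg, "maxSteps must be >= 1")
  if (abs(object@curvatureThreshold) > 1)
    msg <- c(msg, "curvatureThreshold must lie in [-1, 1]")
  if (object@dispersionDeg < 0) msg <- c(msg, "dispersionDeg must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DirectionField: principal fiber directions on a voxel grid
#'
#' A simplified stand-in for voxelwise fiber-orientation distributions: one
#' principal unit direction per voxel (zero vector where undefined) plus an
#' inclusion mask that streamlines must remain inside.
#'
#' @slot vectors 4-D array (nx, ny, nz, 3) of unit (or zero) vectors.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot inclusionMask 3-D 0/1 array matching the grid.
#' @export
setClass("DirectionField", representation(
  vectors = "array", affine = "matrix", inclusionMask = "array"))

setValidity("DirectionField", function(object) {
  msg <- character()
  dv <- dim(object@vectors)
  if (length(dv) != 4L || dv[4] != 3L)
    msg <- c(msg, "vectors must be an (nx, ny, nz, 3) array")
  if (!identical(dim(object@inclusionMask), dv[1:3]))
    msg <- c(msg, "inclusionMask shape must match the vector grid")
  nrm <- sqrt(apply(object@vectors^2, c(1, 2, 3), sum))
  bad <- nrm > 1e-12 & abs(nrm - 1) > 1e-6
  if (any(bad))
    msg <- c(msg, "nonzero direction vectors must have unit norm (tol 1e-6)")
  aff <- .checkAffine(object@affine)
  if (!is.null(aff)) msg <- c(msg, aff)
  if (length(msg)) msg else TRUE
})

#' VisitationMap: per-seed-ROI streamline visitation counts
#'
#' A 3-D volume counting, for one seeded ROI, how many streamlines visited
#' each voxel (each streamline counts once per voxel). With distance
#' correction the increments are weighted by path length and counts are real.
#'
#' @slot seedRoi integer label of the seeded ROI.
#' @slot counts 3-D array of non-negative counts.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot params the [TrackingParams] used (may be a default placeholder for
#'   externally loaded maps).
#' @export
setClass("VisitationMap", representation(
  seedRoi = "integer", counts = "array", affine = "matrix",
  params = "TrackingParams"))

setValidity("VisitationMap", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3L)
    msg <- c(msg, "counts must be a 3-D array")
  if (any(object@counts < 0))
    msg <- c(msg, "negative count")
  if (!object@params@distanceCorrection &&
      any(abs(object@counts - round(object@counts)) > 1e-9))
    msg <- c(msg, "counts must be integers when distance correction is off")
  aff <- .checkAffine(object@affine)
  if (!is.null(aff)) msg <- c(msg, aff)
  if (length(msg)) msg else TRUE
})

## GMAC ----------------------------------------------------------------------

#' GMACVolume: a subject's gray matter axonal connectivity map
#'
#' Holds the three stages of the connectivity value at each transition-shell
#' voxel: the raw adjacency-excluded streamline count f, its log transform
#' f' = log(f + 1), and the within-subject min-max normalized value
#' F = (f' - f'min) / (f'max - f'min), where f'min and f'max are the minimal
#' and maximal nonzero log-transformed values across the subject's shell.
#' Voxels with f = 0 carry F = 0 and are flagged in the zero-count mask.
#'
#' @slot raw 3-D array of f values (0 off the shell).
#' @slot logCounts 3-D array of f' values.
#' @slot normalized 3-D array of F values in [0, 1].
#' @slot fPrimeMin,fPrimeMax the normalization range endpoints.
#' @slot zeroMask 3-D 0/1 array marking shell voxels with no measured
#'   connectivity (f = 0), distinct from minimum measured connectivity.
#' @slot shell the [TransitionShell] the map was computed on.
#' @slot affine 4x4 voxel-to-world transform.
#' @seealso [normalizeWithinSubject()], [gmacToStandardSpace()]
#' @export
setClass("GMACVolume", representation(
  raw = "array", logCounts = "array", normalized = "array",
  fPrimeMin = "numeric", fPrimeMax = "numeric", zeroMask = "array",
  shell = "TransitionShell", affine = "matrix"))

setValidity("GMACVolume", function(object) {
  msg <- character()
  if (any(object@raw < 0)) msg <- c(msg, "raw counts must be >= 0")
  if (max(abs(object@logCounts - log1p(object@raw))) > 1e-8)
    msg <- c(msg, "logCounts must equal log(raw + 1)")
  if (object@fPrimeMin > object@fPrimeMax)
    msg <- c(msg, "fPrimeMin must be <= fPrimeMax")
  nz <- object@normalized[object@raw > 0]
  if (length(nz) && (min(nz) < -1e-12 || max(nz) > 1 + 1e-12))
    msg <- c(msg, "normalized values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## Statistics ----------------------------------------------------------------

#' StatMap: voxelwise correlation statistics across subjects
#'
#' Voxelwise Pearson correlation between subject covariate values and map
#' values, with Fisher-transformed z-scores. Voxels outside the analysis mask
#' carry `NA`, never silent zeros.
#'
#' @slot r 3-D array of correlation coefficients (NA outside mask).
#' @slot z 3-D array of z = atanh(r) * sqrt(n - 3).
#' @slot q 3-D array of Benjamini-Hochberg q-values (all NA unless requested).
#' @slot nPerVoxel 3-D integer array of subjects contributing per voxel.
#' @slot mask 3-D 0/1 array of analyzed voxels.
#' @slot threshold z cutoff applied downstream (NA until thresholding).
#' @slot affine 4x4 voxel-to-world transform.
#' @seealso [voxelwiseCorrelation()], [thresholdMap()]
#' @export
setClass("StatMap", representation(
  r = "array", z = "array", q = "array", nPerVoxel = "array", mask = "array",
  threshold = "numeric", affine = "matrix"))

setValidity("StatMap", function(object) {
  msg <- character()
  rin <- object@r[object@mask > 0]
  if (length(rin) && any(abs(rin) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "|r| must be <= 1 inside the mask")
  zin <- object@z[object@mask > 0 & object@nPerVoxel >= 4]
  if (length(zin) && any(!is.finite(zin)))
    msg <- c(msg, "z must be finite wherever n >= 4 inside the mask")
  if (length(msg)) msg else TRUE
})

## Phantom specifications ----------------------------------------------------

#' PhantomSpec: recipe for a synthetic brain phantom
#'
#' Describes a labeled parcellation of compact gray matter blobs inside a
#' brain mask, the complementary white matter, and straight fiber bundles
#' (tubes between ROI centers) carrying a direction field.
#'
#' @slot gridShape integer triple.
#' @slot nRois number of gray matter ROIs (>= 2).
#' @slot bundles list of bundle descriptions, each a list with elements
#'   `from`, `to` (distinct ROI labels), optional `radius` (voxels, default 0
#'   = single-voxel column) and `dispersionDeg`.
#' @slot roiRadius gray blob radius in voxels.
#' @slot noiseLevel reserved amplitude for count noise (>= 0).
#' @slot seed integer seed; fixed seed gives byte-identical phantoms.
#' @seealso [makePhantom()]
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer", nRois = "integer", bundles = "list",
  roiRadius = "numeric", noiseLevel = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@nRois < 2L) msg <- c(msg, "nRois must be >= 2")
  if (object@noiseLevel < 0) msg <- c(msg, "noiseLevel must be >= 0")
  if (any(object@gridShape < 8L))
    msg <- c(msg, "grid too small to hold ROIs plus a white matter margin")
  for (b in object@bundles) {
    if (is.null(b$from) || is.null(b$to) || b$from == b$to ||
        b$from < 1L || b$to < 1L || b$from > object@nRois || b$to > object@nRois)
      msg <- c(msg, "each bundle must reference two distinct existing ROIs")
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: recipe for a synthetic multi-subject cohort
#'
#' Defines subjects whose normalized connectivity maps are the template
#' phantom's map plus a planted linear covariate effect at chosen shell voxels
#' plus Gaussian noise, clamped to [0, 1].
#'
#' @slot nSubjects number of subjects.
#' @slot covariateName e.g. "age".
#' @slot covariateRange (low, high); covariates are drawn uniformly.
#' @slot effectVoxels m x 3 integer matrix of 0-based shell voxel indices.
#' @slot slope change in F per covariate unit at the effect voxels.
#' @slot noiseSd Gaussian noise sd added at shell voxels (>= 0; 0 gives the
#'   deterministic degenerate cohort).
#' @slot seed integer seed.
#' @seealso [makeCohort()]
#' @export
setClass("CohortSpec", representation(
  nSubjects = "integer", covariateName = "character",
  covariateRange = "numeric", effectVoxels = "matrix", slope = "numeric",
  noiseSd = "numeric", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@covariateRange) != 2L ||
      diff(object@covariateRange) <= 0)
    msg <- c(msg, "covariateRange must be an increasing (low, high) pair")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (ncol(object@effectVoxels) != 3L)
    msg <- c(msg, "effectVoxels must be an m x 3 index matrix")
  if (length(msg)) msg else TRUE
})
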