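#' Voxel data of a volume
#' @param x a [BrainVolume-class] derivative.
#' @return the underlying 3-D array.
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' World affine of an object on a voxel grid
#' @param x a volume, shell, field, map or statistic object.
#' @return the 4x4 voxel-index (0-based) to mm transform.
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))

#' Voxel size in mm per axis
#' @param x a [BrainVolume-class] derivative.
#' @return numeric triple of strictly positive voxel edge lengths (mm).
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname volData
#' @export
setMethod("volData", "BrainVolume", function(x) x@data)

#' @rdname volAffine
#' @export
setMethod("volAffine", "BrainVolume", function(x) x@affine)

#' @rdname volAffine
#' @export
setMethod("volAffine", "TransitionShell", function(x) x@affine)

#' @rdname volAffine
#' @export
setMethod("volAffine", "DirectionField", function(x) x@affine)

#' @rdname volAffine
#' @export
setMethod("volAffine", "VisitationMap", function(x) x@affine)

#' @rdname volAffine
#' @export
setMethod("volAffine", "GMACVolume", function(x) x@affine)

#' @rdname volAffine
#' @export
setMethod("volAffine", "StatMap", function(x) x@affine)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "BrainVolume", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))

#' Shell voxel indices
#' @param x a [TransitionShell-class].
#' @return n x 3 integer matrix of 0-based voxel indices.
#' @export
setGeneric("shellVoxels", function(x) standardGeneric("shellVoxels"))

#' @rdname shellVoxels
#' @export
setMethod("shellVoxels", "TransitionShell", function(x) x@voxels)

#' Shell ROI assignments
#' @param x a [TransitionShell-class].
#' @return integer vector of assigned ROI labels, parallel to
#'   [shellVoxels()].
#' @export
setGeneric("shellLabels", function(x) standardGeneric("shellLabels"))

#' @rdname shellLabels
#' @export
setMethod("shellLabels", "TransitionShell", function(x) x@labels)

#' Raw adjacency-excluded counts of a GMAC
#' @param x a [GMACVolume-class].
#' @return 3-D array of f values.
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname rawCounts
#' @export
setMethod("rawCounts", "GMACVolume", function(x) x@raw)

#' @rdname rawCounts
#' @export
setMethod("rawCounts", "VisitationMap", function(x) x@counts)

#' Normalized connectivity values of a GMAC
#' @param x a [GMACVolume-class].
#' @return 3-D array of F values in [0, 1].
#' @export
setGeneric("normalizedMap", function(x) standardGeneric("normalizedMap"))

#' @rdname normalizedMap
#' @export
setMethod("normalizedMap", "GMACVolume", function(x) x@normalized)

#' Within-subject normalization range
#' @param x a [GMACVolume-class].
#' @return named numeric c(fPrimeMin =, fPrimeMax =).
#' @export
setGeneric("normalizationRange", function(x)
  standardGeneric("normalizationRange"))

#' @rdname normalizationRange
#' @export
setMethod("normalizationRange", "GMACVolume", function(x)
  c(fPrimeMin = x@fPrimeMin, fPrimeMax = x@fPrimeMax))

## show methods --------------------------------------------------------------

setMethod("show", "LabelVolume", function(object) {
  labs <- sort(unique(as.vector(object@data)))
  labs <- labs[labs > 0]
  cat("LabelVolume", paste(dim(object@data), collapse = " x "),
      sprintf("| %d label(s), voxel size %s mm\n", length(labs),
              paste(signif(voxelSize(object), 3), collapse = " x ")))
})

setMethod("show", "ScalarVolume", function(object) {
  rng <- range(object@data, na.rm = TRUE)
  cat("ScalarVolume", paste(dim(object@data), collapse = " x "),
      sprintf("| range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "AffineTransform", function(object) {
  cat(sprintf("AffineTransform: %s -> %s\n", object@sourceSpace,
              object@targetSpace))
  print(signif(object@matrix, 6))
})

setMethod("show", "TransitionShell", function(object) {
  cat(sprintf(
    "TransitionShell: %d voxel(s), %d ROI(s), grid %s (tie seed %d)\n",
    nrow(object@voxels), length(unique(object@labels)),
    paste(object@gridShape, collapse = " x "), object@seed))
})

setMethod("show", "TrackingParams", function(object) {
  cat(sprintf(paste0(
    "TrackingParams: %d samples/seed voxel, curvature >= %.2f, ",
    "<= %d steps of %.2f mm\n  distance correction %s, dispersion %.1f deg, ",
    "bidirectional %s, seed %d\n"),
    object@nSamples, object@curvatureThreshold, object@maxSteps,
    object@stepLengthMm, if (object@distanceCorrection) "on" else "off",
    object@dispersionDeg, if (object@bidirectional) "on" else "off",
    object@seed))
})

setMethod("show", "VisitationMap", function(object) {
  cat(sprintf("VisitationMap: seed ROI %d, %d visited voxel(s), total %.6g\n",
              object@seedRoi, sum(object@counts > 0), sum(object@counts)))
})

setMethod("show", "GMACVolume", function(object) {
  cat(sprintf(paste0(
    "GMACVolume on a %d-voxel shell: %d voxel(s) with signal, ",
    "f' range [%.4g, %.4g]\n"),
    nrow(object@shell@voxels), sum(object@raw > 0),
    object@fPrimeMin, object@fPrimeMax))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: %d voxel(s) in mask, z range [%.3g, %.3g]\n",
              sum(object@mask > 0),
              suppressWarnings(min(object@z, na.rm = TRUE)),
              suppressWarnings(max(object@z, na.rm = TRUE))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: grid %s, %d ROIs, %d bundle(s), seed %d\n",
              paste(object@gridShape, collapse = " x "), object@nRois,
              length(object@bundles), object@seed))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d subjects, %s in [%g, %g], slope %g, noise sd %g\n",
    object@nSubjects, object@covariateName, object@covariateRange[1],
    object@covariateRange[2], object@slope, object@noiseSd))
})
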