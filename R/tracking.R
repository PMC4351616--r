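#' Construct tracking parameters
#'
#' Defaults are the standard probabilistic-tractography settings: 5000
#' pathways per seed voxel, curvature threshold 0.2 (minimum cosine between
#' successive step directions), 200 maximum steps, 0.5 mm steps, distance
#' correction enabled, bidirectional seeding.
#'
#' @param nSamples streamlines per seed voxel.
#' @param curvatureThreshold minimum cosine between successive steps.
#' @param maxSteps maximum steps per streamline.
#' @param stepLengthMm step length, mm.
#' @param distanceCorrection logical; weight each voxel's increment by the
#'   streamline path length (mm) at first visit.
#' @param dispersionDeg sd (degrees) of the Gaussian angular jitter applied
#'   to the field direction at each step; 0 gives deterministic paths.
#' @param bidirectional propagate both field polarities from each seed.
#' @param seed integer RNG seed.
#' @return a [TrackingParams-class].
#' @export
trackingParams <- function(nSamples = 5000L, curvatureThreshold = 0.2,
                           maxSteps = 200L, stepLengthMm = 0.5,
                           distanceCorrection = TRUE, dispersionDeg = 0,
                           bidirectional = TRUE, seed = 0L) {
  new("TrackingParams", nSamples = as.integer(nSamples),
      curvatureThreshold = curvatureThreshold, maxSteps = as.integer(maxSteps),
      stepLengthMm = stepLengthMm, distanceCorrection = distanceCorrection,
      dispersionDeg = dispersionDeg, bidirectional = bidirectional,
      seed = as.integer(seed))
}

#' Construct a direction field
#' @param vectors (nx, ny, nz, 3) array; nonzero vectors must be unit norm.
#' @param inclusionMask 3-D 0/1 array; streamlines terminate on leaving it.
#' @param affine 4x4 voxel-to-world transform.
#' @return a [DirectionField-class].
#' @export
directionField <- function(vectors, inclusionMask, affine = diag(4)) {
  new("DirectionField", vectors = vectors, affine = affine,
      inclusionMask = array(as.integer(inclusionMask != 0),
                            dim = dim(inclusionMask)))
}

# Nearest-voxel lookup helpers. floor(x + 0.5) rather than round() so
# half-integer boundary positions resolve consistently toward +infinity.
.nearestVoxel <- function(x) as.integer(floor(x + 0.5))

.fieldVoxel <- function(field, mm) {
  .nearestVoxel(worldToVoxelIdx(mm, field@affine))
}

.insideMask <- function(field, vox) {
  shp <- dim(field@inclusionMask)
  all(vox >= 0L) && all(vox < shp) &&
    field@inclusionMask[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L] == 1L
}

.fieldAt <- function(field, vox) {
  field@vectors[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L, ]
}

# Gaussian angular jitter: rotate `d` by |N(0, sd)| radians about a uniform
# perpendicular axis. sd given in degrees.
.jitterDirection <- function(d, dispersionDeg) {
  if (dispersionDeg <= 0) return(d)
  theta <- stats::rnorm(1, 0, dispersionDeg * pi / 180)
  u <- stats::rnorm(3)
  u <- u - sum(u * d) * d
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(d)
  u <- u / nu
  v <- cos(theta) * d + sin(theta) * u
  v / sqrt(sum(v^2))
}

#' Propagate one streamline through a direction field
#'
#' Fixed-step integration along the voxelwise principal direction, optionally
#' jittered. Each candidate direction is sign-aligned with the previous step;
#' the streamline terminates on leaving the inclusion mask, entering a
#' zero-vector voxel, exceeding the curvature threshold (cosine between
#' successive step directions below `curvatureThreshold`), or after
#' `maxSteps` steps.
#'
#' @param field a [DirectionField-class].
#' @param startMm starting position (mm), inside the inclusion mask.
#' @param params a [TrackingParams-class].
#' @param polarity +1 or -1, the initial direction polarity.
#' @return matrix of mm positions (one row per point, at most maxSteps + 1).
#' @export
propagateStreamline <- function(field, startMm, params = trackingParams(),
                                polarity = 1) {
  stopifnot(is(field, "DirectionField"), is(params, "TrackingParams"))
  vox <- .fieldVoxel(field, startMm)
  if (!.insideMask(field, vox))
    stopf("streamline start (%s) outside the inclusion mask",
          paste(signif(startMm, 4), collapse = ", "))
  path <- matrix(0, params@maxSteps + 1L, 3L)
  path[1L, ] <- startMm
  npts <- 1L
  pos <- startMm
  prevDir <- NULL
  for (step in seq_len(params@maxSteps)) {
    v <- .fieldAt(field, vox)
    if (sum(v^2) < 1e-12) break
    if (is.null(prevDir)) {
      v <- polarity * v
    } else if (sum(v * prevDir) < 0) {
      v <- -v
    }
    d <- .jitterDirection(v, params@dispersionDeg)
    if (!is.null(prevDir) && sum(d * prevDir) < params@curvatureThreshold)
      break
    nxt <- pos + params@stepLengthMm * d
    nvox <- .fieldVoxel(field, nxt)
    if (!.insideMask(field, nvox)) break
    npts <- npts + 1L
    path[npts, ] <- nxt
    pos <- nxt
    vox <- nvox
    prevDir <- d
  }
  path[seq_len(npts), , drop = FALSE]
}

# Unique voxels visited by a path, with the path length (mm) at first visit.
.pathVisits <- function(field, path, stepLengthMm) {
  if (!nrow(path)) return(list(lin = integer(), len = numeric()))
  vox <- matrix(.nearestVoxel(worldToVoxelIdx(path, field@affine)),
                ncol = 3)
  lin <- linearIndex(vox, dim(field@inclusionMask))
  first <- !duplicated(lin)
  list(lin = as.integer(lin[first]),
       len = (which(first) - 1) * stepLengthMm)
}

#' Track from every shell voxel of one ROI
#'
#' Launches `nSamples` streamlines from the center of each shell voxel
#' assigned to `roi` (both field polarities when bidirectional) and
#' accumulates a visitation-count volume: each streamline increments each
#' voxel it visits once; with distance correction the increment is the
#' streamline's path length in mm at first visit. Deterministic for a fixed
#' `params@seed`.
#'
#' @param field a [DirectionField-class].
#' @param shell a [TransitionShell-class] on the same grid.
#' @param roi ROI label present in the shell.
#' @param params a [TrackingParams-class].
#' @return a [VisitationMap-class].
#' @export
seedRoiTracking <- function(field, shell, roi, params = trackingParams()) {
  stopifnot(is(field, "DirectionField"), is(shell, "TransitionShell"))
  roi <- as.integer(roi)
  seedIdx <- shell@voxels[shell@labels == roi, , drop = FALSE]
  if (!nrow(seedIdx))
    stopf("ROI %d is absent from the shell", roi)
  shp <- dim(field@inclusionMask)
  counts <- numeric(prod(shp))
  polarities <- if (params@bidirectional) c(1, -1) else 1
  withSeed(params@seed, {
    for (sv in seq_len(nrow(seedIdx))) {
      startMm <- drop(voxelToWorldMm(seedIdx[sv, , drop = FALSE],
                                     field@affine))
      if (!.insideMask(field, .fieldVoxel(field, startMm)))
        next
      # zero dispersion: every sample retraces the same path
      nEff <- if (params@dispersionDeg <= 0) 1L else params@nSamples
      mult <- if (params@dispersionDeg <= 0) params@nSamples else 1L
      for (s in seq_len(nEff)) {
        lin <- integer(); len <- numeric()
        for (pol in polarities) {
          p <- propagateStreamline(field, startMm, params, polarity = pol)
          vis <- .pathVisits(field, p, params@stepLengthMm)
          keep <- !(vis$lin %in% lin)
          lin <- c(lin, vis$lin[keep])
          len <- c(len, vis$len[keep])
        }
        if (params@distanceCorrection) {
          counts[lin] <- counts[lin] + mult * len
        } else {
          counts[lin] <- counts[lin] + mult
        }
      }
    }
  })
  new("VisitationMap", seedRoi = roi,
      counts = array(counts, dim = shp), affine = field@affine,
      params = params)
}

#' Load externally computed visitation maps
#'
#' Reads one NIfTI count volume per seeded ROI (e.g. outputs of an external
#' probabilistic tractography run), validating that all files share one grid
#' and contain no negative counts.
#'
#' @param paths NIfTI paths, one per ROI.
#' @param roiLabels integer labels, parallel to `paths`.
#' @param params optional [TrackingParams-class] provenance to attach;
#'   defaults to distance-corrected settings so real-valued counts validate.
#' @return list of [VisitationMap-class], in `roiLabels` order.
#' @export
loadVisitationMaps <- function(paths, roiLabels,
                               params = trackingParams()) {
  if (length(paths) != length(roiLabels))
    stopf("%d paths but %d ROI labels", length(paths), length(roiLabels))
  maps <- vector("list", length(paths))
  ref <- NULL
  for (i in seq_along(paths)) {
    vol <- readScalarVolume(paths[i])
    if (any(vol@data < 0))
      stopf("negative count in %s", paths[i])
    if (is.null(ref)) {
      ref <- vol
    } else if (!identical(dim(vol@data), dim(ref@data)) ||
               max(abs(vol@affine - ref@affine)) > 1e-6) {
      stopf("grid mismatch: %s does not match %s", paths[i], paths[1])
    }
    maps[[i]] <- new("VisitationMap", seedRoi = as.integer(roiLabels[i]),
                     counts = vol@data, affine = vol@affine, params = params)
  }
  maps
}

#' Write a visitation map as NIfTI
#' @param map a [VisitationMap-class].
#' @param dir output directory; the file is named
#'   `seed_<label>_paths.nii.gz`.
#' @return the file path, invisibly.
#' @export
writeVisitationMap <- function(map, dir) {
  stopifnot(is(map, "VisitationMap"))
  path <- file.path(dir, sprintf("seed_%d_paths.nii.gz", map@seedRoi))
  writeVolume(scalarVolume(map@counts, affine = map@affine), path)
  invisible(path)
}

#' Serialize tracking parameters to a flat key=value config file
#' @param params a [TrackingParams-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrackingParams <- function(params, path) {
  stopifnot(is(params, "TrackingParams"))
  writeLines(c(
    sprintf("n_samples = %d", params@nSamples),
    sprintf("curvature_threshold = %.17g", params@curvatureThreshold),
    sprintf("max_steps = %d", params@maxSteps),
    sprintf("step_length_mm = %.17g", params@stepLengthMm),
    sprintf("distance_correction = %s",
            tolower(as.character(params@distanceCorrection))),
    sprintf("dispersion_deg = %.17g", params@dispersionDeg),
    sprintf("bidirectional = %s", tolower(as.character(params@bidirectional))),
    sprintf("seed = %d", params@seed)), path)
  invisible(path)
}

#' Read tracking parameters from a flat key=value config file
#' @param path config path as written by [writeTrackingParams()].
#' @return a [TrackingParams-class].
#' @export
readTrackingParams <- function(path) {
  kv <- readFlatConfig(path)
  pick <- function(key, default) if (key %in% names(kv)) kv[[key]] else default
  trackingParams(
    nSamples = as.integer(pick("n_samples", 5000)),
    curvatureThreshold = as.numeric(pick("curvature_threshold", 0.2)),
    maxSteps = as.integer(pick("max_steps", 200)),
    stepLengthMm = as.numeric(pick("step_length_mm", 0.5)),
    distanceCorrection = as.logical(toupper(pick("distance_correction",
                                                 "true"))),
    dispersionDeg = as.numeric(pick("dispersion_deg", 0)),
    bidirectional = as.logical(toupper(pick("bidirectional", "true"))),
    seed = as.integer(pick("seed", 0)))
}
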