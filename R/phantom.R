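#' Construct a phantom specification
#'
#' @param gridShape integer triple (default 24 cubed).
#' @param nRois number of gray matter ROIs (>= 2).
#' @param bundles list of bundles, each `list(from =, to =, radius = 0,
#'   dispersionDeg = 0)`; `radius` is the tube radius in voxels (0 gives a
#'   single-voxel column).
#' @param roiRadius gray blob radius in voxels.
#' @param noiseLevel reserved count-noise amplitude (>= 0).
#' @param seed integer seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(gridShape = c(24L, 24L, 24L), nRois = 2L,
                        bundles = list(list(from = 1L, to = 2L)),
                        roiRadius = 3, noiseLevel = 0, seed = 0L) {
  bundles <- lapply(bundles, function(b) {
    b$from <- as.integer(b$from); b$to <- as.integer(b$to)
    if (is.null(b$radius)) b$radius <- 0
    if (is.null(b$dispersionDeg)) b$dispersionDeg <- 0
    b
  })
  new("PhantomSpec", gridShape = as.integer(gridShape),
      nRois = as.integer(nRois), bundles = bundles, roiRadius = roiRadius,
      noiseLevel = noiseLevel, seed = as.integer(seed))
}

# Deterministic ROI centers: a coarse lattice inside the brain box, ordered
# x-fastest so small phantoms line their ROIs up along the x axis (straight
# axis-aligned bundles for the canonical two-ROI phantom).
.phantomCenters <- function(spec) {
  shp <- spec@gridShape
  r <- spec@roiRadius
  lo <- r + 2          # 1-voxel brain margin + 1-voxel white rim
  axes <- lapply(shp, function(n) {
    hi <- n - 1 - r - 2
    if (hi < lo) return(numeric())
    seq(lo, hi, by = max(2 * r + 3, 1))
  })
  cand <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  if (nrow(cand) < spec@nRois)
    stopf("grid %s too small for %d ROIs of radius %g",
          paste(shp, collapse = "x"), spec@nRois, r)
  cand[seq_len(spec@nRois), , drop = FALSE]
}

#' Generate a synthetic brain phantom
#'
#' Builds, deterministically for a fixed spec, a labeled parcellation of
#' compact spherical gray matter ROIs inside a brain mask, the complementary
#' white matter mask, and a direction field that follows each bundle's axis
#' inside a straight tube between the two ROI centers (zero elsewhere). The
#' brain mask doubles as the tracking inclusion mask.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `parcellation` ([LabelVolume-class]),
#'   `wmMask` ([LabelVolume-class]), `field` ([DirectionField-class]).
#' @examples
#' ph <- makePhantom(phantomSpec())
#' ph$parcellation
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  shp <- spec@gridShape
  idx <- gridIndices(shp)
  brain <- idx[, 1] >= 1 & idx[, 1] <= shp[1] - 2 &
    idx[, 2] >= 1 & idx[, 2] <= shp[2] - 2 &
    idx[, 3] >= 1 & idx[, 3] <= shp[3] - 2
  centers <- .phantomCenters(spec)
  lab <- integer(prod(shp))
  for (k in seq_len(spec@nRois)) {
    d2 <- (idx[, 1] - centers[k, 1])^2 + (idx[, 2] - centers[k, 2])^2 +
      (idx[, 3] - centers[k, 3])^2
    inside <- d2 <= spec@roiRadius^2
    if (any(lab[inside] > 0L))
      stopf("overlapping ROI geometry between ROI %d and ROI %d",
            max(lab[inside]), k)
    lab[inside] <- k
  }
  gray <- array(lab, dim = shp)
  wm <- array(as.integer(brain & lab == 0L), dim = shp)
  vecs <- array(0, dim = c(shp, 3L))
  for (b in spec@bundles) {
    a <- centers[b$from, ]; z <- centers[b$to, ]
    u <- z - a
    L <- sqrt(sum(u^2))
    u <- u / L
    rel <- sweep(idx, 2, a)
    t <- as.vector(rel %*% u)
    perp2 <- rowSums(rel^2) - t^2
    inTube <- t >= 0 & t <= L & perp2 <= (b$radius + 0.5)^2
    for (ax in 1:3) {
      comp <- vecs[, , , ax]
      comp[inTube] <- u[ax]
      vecs[, , , ax] <- comp
    }
  }
  list(parcellation = labelVolume(gray),
       wmMask = labelVolume(wm),
       field = directionField(vecs, array(as.integer(brain), dim = shp)))
}

#' Construct a cohort specification
#'
#' Defaults emulate a small healthy-adult cohort: 18 subjects with an age
#' covariate drawn uniformly on 30-51 years (midlife, matching a mean near
#' 40.5), a planted linear age effect at chosen shell voxels, and Gaussian
#' map noise.
#'
#' @param nSubjects number of subjects.
#' @param covariateName covariate label.
#' @param covariateRange uniform sampling range (low, high).
#' @param effectVoxels m x 3 matrix of 0-based shell voxel indices.
#' @param slope change in F per covariate unit at the effect voxels.
#' @param noiseSd Gaussian noise sd on shell voxels (0 allowed: the
#'   deterministic degenerate cohort).
#' @param seed integer seed.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 18L, covariateName = "age",
                       covariateRange = c(30, 51),
                       effectVoxels = matrix(integer(), 0, 3),
                       slope = -0.005, noiseSd = 0.02, seed = 0L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      covariateName = covariateName, covariateRange = covariateRange,
      effectVoxels = effectVoxels, slope = slope, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Generate a synthetic multi-subject cohort of connectivity maps
#'
#' Computes the template phantom's GMAC once (shell construction, simplified
#' tracking, adjacency-excluded counting, normalization), then derives each
#' subject's map as template F plus a planted linear covariate effect at the
#' chosen shell voxels plus Gaussian noise on all shell voxels, clamped to
#' [0, 1]. Covariates are drawn uniformly over the cohort range. Fully
#' deterministic for fixed seeds.
#'
#' @param template a [PhantomSpec-class].
#' @param cohort a [CohortSpec-class]; its `effectVoxels` must lie on the
#'   template's shell.
#' @param params [TrackingParams-class] for the template tracking; defaults
#'   to a desk-scale 50 samples/voxel, integer counts.
#' @return list with elements `subjects` (list of `list(subjectId, map,
#'   covariate)`), `template` (the template [GMACVolume-class]) and `shell`.
#' @export
makeCohort <- function(template, cohort,
                       params = trackingParams(nSamples = 50L,
                                               distanceCorrection = FALSE,
                                               seed = 0L)) {
  stopifnot(is(template, "PhantomSpec"), is(cohort, "CohortSpec"))
  if (cohort@noiseSd < 0) stopf("noiseSd must be >= 0")
  ph <- makePhantom(template)
  shell <- buildShell(ph$parcellation, ph$wmMask, seed = template@seed)
  rois <- sort(unique(shellLabels(shell)))
  maps <- lapply(rois, function(k)
    seedRoiTracking(ph$field, shell, k, params))
  gmac <- suppressWarnings(computeGMAC(shell, maps))
  tmplF <- gmac@normalized
  shp <- shell@gridShape
  shellLin <- linearIndex(shell@voxels, shp)
  eff <- cohort@effectVoxels
  if (nrow(eff)) {
    effLin <- linearIndex(eff, shp)
    if (!all(effLin %in% shellLin))
      stopf("effect voxels must lie on the template shell")
  } else {
    effLin <- integer()
  }
  mid <- mean(cohort@covariateRange)
  subjects <- withSeed(cohort@seed, {
    covs <- stats::runif(cohort@nSubjects, cohort@covariateRange[1],
                         cohort@covariateRange[2])
    lapply(seq_len(cohort@nSubjects), function(s) {
      m <- tmplF
      if (length(effLin))
        m[effLin] <- m[effLin] + cohort@slope * (covs[s] - mid)
      if (cohort@noiseSd > 0)
        m[shellLin] <- m[shellLin] +
          stats::rnorm(length(shellLin), 0, cohort@noiseSd)
      m[m < 0] <- 0
      m[m > 1] <- 1
      list(subjectId = sprintf("sub%03d", s),
           map = scalarVolume(m, affine = shell@affine),
           covariate = covs[s])
    })
  })
  list(subjects = subjects, template = gmac, shell = shell)
}

#' Write a cohort as NIfTI volumes plus a covariate table
#'
#' One `<subjectId>_gmac.nii.gz` per subject and a tab-separated
#' `cohort.tsv` with columns `subject_id` and the covariate.
#'
#' @param cohortData result of [makeCohort()].
#' @param dir output directory (created if needed).
#' @param covariateName column name for the covariate.
#' @return path of the covariate table, invisibly.
#' @export
writeCohort <- function(cohortData, dir, covariateName = "age") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(
    subject_id = vapply(cohortData$subjects, `[[`, "", "subjectId"),
    covariate = vapply(cohortData$subjects, `[[`, 0, "covariate"))
  names(tab)[2] <- covariateName
  for (s in cohortData$subjects)
    writeVolume(s$map, file.path(dir, paste0(s$subjectId, "_gmac.nii.gz")))
  tsv <- file.path(dir, "cohort.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv)
}
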