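#' Sum streamline counts from all non-adjacent ROIs at each shell voxel
#'
#' At a shell voxel assigned to ROI k, the connectivity count f is the sum of
#' visitation counts at that voxel over the maps of every seeded ROI except k
#' itself — the region immediately adjacent to the voxel is excluded so a
#' region's own seeding cannot inflate its cortical connectivity. Voxels off
#' the shell get 0.
#'
#' @param shell a [TransitionShell-class].
#' @param maps list of [VisitationMap-class], covering every ROI label
#'   present in the shell; all on the shell's grid.
#' @return a [ScalarVolume-class] of f values.
#' @export
sumNonlocalCounts <- function(shell, maps) {
  stopifnot(is(shell, "TransitionShell"))
  labs <- vapply(maps, function(m) m@seedRoi, integer(1))
  if (anyDuplicated(labs))
    stopf("duplicate visitation maps for ROI %d", labs[anyDuplicated(labs)])
  need <- sort(unique(shell@labels))
  missing <- setdiff(need, labs)
  if (length(missing))
    stopf("no visitation map for shell ROI %d", missing[1])
  shp <- shell@gridShape
  for (m in maps) {
    if (!identical(dim(m@counts), shp) ||
        max(abs(m@affine - shell@affine)) > 1e-6)
      stopf("grid mismatch between shell and visitation map for ROI %d",
            m@seedRoi)
  }
  total <- Reduce(`+`, lapply(maps, function(m) as.vector(m@counts)))
  f <- numeric(prod(shp))
  lin <- linearIndex(shell@voxels, shp)
  f[lin] <- total[lin]
  for (k in need) {
    ownLin <- lin[shell@labels == k]
    own <- as.vector(maps[[match(k, labs)]]@counts)
    f[ownLin] <- f[ownLin] - own[ownLin]
  }
  scalarVolume(array(f, dim = shp), affine = shell@affine)
}

#' Log-transform streamline counts
#'
#' Elementwise f' = log(f + 1) (natural log). The +1 offset keeps zero counts
#' at zero; the log base is immaterial for the normalized map because base
#' changes cancel in min-max scaling.
#'
#' @param fVol a [ScalarVolume-class] of non-negative counts.
#' @return a [ScalarVolume-class] of f' values.
#' @export
logTransform <- function(fVol) {
  stopifnot(is(fVol, "ScalarVolume"))
  if (any(fVol@data < 0))
    stopf("negative count %g passed to logTransform", min(fVol@data))
  scalarVolume(log1p(fVol@data), affine = fVol@affine)
}

# Shell voxels carrying measured connectivity: integer counts need f >= 1
# (f' > 0); real-valued distance-corrected counts need f > 0.
.nonzeroCounts <- function(f) {
  if (all(abs(f - round(f)) < 1e-9)) f >= 1 else f > 0
}

#' Min-max normalize a subject's log counts
#'
#' F = (f' - f'min) / (f'max - f'min), where f'min and f'max are the minimal
#' and maximal nonzero log-transformed values over the subject's shell
#' voxels. Shell voxels with f = 0 receive F = 0 and are flagged in the
#' zero-count mask ("no measured connectivity", distinct from minimum
#' measured connectivity). When every nonzero voxel carries the same count
#' the min-max range collapses; all those voxels then attain the maximum and
#' receive F = 1 (with a warning).
#'
#' @param fPrimeVol [ScalarVolume-class] of f' values (from [logTransform()]).
#' @param shell the [TransitionShell-class] f was computed on.
#' @param fVol [ScalarVolume-class] of raw f values.
#' @return a [GMACVolume-class].
#' @export
normalizeWithinSubject <- function(fPrimeVol, shell, fVol) {
  stopifnot(is(fPrimeVol, "ScalarVolume"), is(shell, "TransitionShell"),
            is(fVol, "ScalarVolume"))
  if (max(abs(fPrimeVol@data - log1p(fVol@data))) > 1e-8)
    stopf("f' volume is not log(f + 1) of the raw count volume")
  shp <- shell@gridShape
  lin <- linearIndex(shell@voxels, shp)
  f <- fVol@data[lin]
  fp <- fPrimeVol@data[lin]
  nz <- .nonzeroCounts(f)
  if (!any(nz))
    stopf("no connectivity signal: all shell voxels have f = 0")
  fpMin <- min(fp[nz])
  fpMax <- max(fp[nz])
  Fvals <- numeric(length(lin))
  if (fpMax - fpMin < 1e-12) {
    warning("degenerate normalization range: all nonzero counts equal; ",
            "assigning F = 1 at nonzero voxels", call. = FALSE)
    Fvals[nz] <- 1
  } else {
    Fvals[nz] <- (fp[nz] - fpMin) / (fpMax - fpMin)
  }
  Farr <- array(0, dim = shp)
  Farr[lin] <- Fvals
  zero <- array(0L, dim = shp)
  zero[lin[!nz]] <- 1L
  new("GMACVolume", raw = fVol@data, logCounts = fPrimeVol@data,
      normalized = Farr, fPrimeMin = fpMin, fPrimeMax = fpMax,
      zeroMask = zero, shell = shell, affine = shell@affine)
}

#' Compute a subject's GMAC in one call
#'
#' Convenience wrapper: [sumNonlocalCounts()], [logTransform()],
#' [normalizeWithinSubject()].
#'
#' @inheritParams sumNonlocalCounts
#' @return a [GMACVolume-class].
#' @export
computeGMAC <- function(shell, maps) {
  f <- sumNonlocalCounts(shell, maps)
  normalizeWithinSubject(logTransform(f), shell, f)
}

#' Resample a GMAC into standard space
#'
#' Composes the native-to-T1 and T1-to-standard affines and applies the
#' composition once with trilinear interpolation; negative interpolation
#' artifacts are clamped to 0.
#'
#' @param gmac a [GMACVolume-class].
#' @param xfmToT1 [AffineTransform-class], native diffusion mm to T1 mm.
#' @param xfmToMni [AffineTransform-class], T1 mm to standard-space mm.
#' @param targetShape integer triple of the standard grid.
#' @param targetAffine 4x4 voxel-to-world transform of the standard grid.
#' @return a [ScalarVolume-class] of normalized values on the target grid.
#' @export
gmacToStandardSpace <- function(gmac, xfmToT1, xfmToMni, targetShape,
                                targetAffine) {
  stopifnot(is(gmac, "GMACVolume"), is(xfmToT1, "AffineTransform"),
            is(xfmToMni, "AffineTransform"))
  comp <- xfmToMni@matrix %*% xfmToT1@matrix
  if (abs(det(comp)) < .Machine$double.eps * 64)
    stopf("singular composed transform")
  xfm <- affineTransform(comp, xfmToT1@sourceSpace, xfmToMni@targetSpace)
  out <- resampleScalar(scalarVolume(gmac@normalized, affine = gmac@affine),
                        xfm, targetShape, targetAffine)
  out@data[out@data < 0] <- 0
  out
}

#' Write a GMAC and its provenance sidecar
#'
#' Writes `<prefix>_gmac_raw.nii.gz` (f), `<prefix>_gmac.nii.gz` (F) and a
#' flat key=value sidecar `<prefix>_gmac.txt` with the normalization range
#' and tie seed.
#'
#' @param gmac a [GMACVolume-class].
#' @param prefix output path prefix (may include a directory).
#' @return named character vector of the three paths, invisibly.
#' @export
writeGMAC <- function(gmac, prefix) {
  stopifnot(is(gmac, "GMACVolume"))
  rawPath <- paste0(prefix, "_gmac_raw.nii.gz")
  fPath <- paste0(prefix, "_gmac.nii.gz")
  sidecar <- paste0(prefix, "_gmac.txt")
  writeVolume(scalarVolume(gmac@raw, affine = gmac@affine), rawPath)
  writeVolume(scalarVolume(gmac@normalized, affine = gmac@affine), fPath)
  writeLines(c(
    sprintf("f_prime_min = %.17g", gmac@fPrimeMin),
    sprintf("f_prime_max = %.17g", gmac@fPrimeMax),
    sprintf("shell_voxels = %d", nrow(gmac@shell@voxels)),
    sprintf("tie_seed = %d", gmac@shell@seed)), sidecar)
  invisible(c(raw = rawPath, normalized = fPath, sidecar = sidecar))
}
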