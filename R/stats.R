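# Half-sample reflection of a 1-based index onto 1..n (the boundary rule
# that keeps a normalized symmetric kernel mass-preserving).
.reflectIndex <- function(t, n) {
  if (n == 1L) return(rep(1L, length(t)))
  period <- 2L * n
  t <- ((t - 1L) %% period) + 1L
  ifelse(t > n, period + 1L - t, t)
}

# n x n convolution matrix for a symmetric kernel with reflective boundaries.
.convMatrix <- function(n, kernel, radius) {
  C <- matrix(0, n, n)
  for (o in -radius:radius) {
    j <- .reflectIndex(seq_len(n) + o, n)
    w <- kernel[o + radius + 1L]
    C[cbind(seq_len(n), j)] <- C[cbind(seq_len(n), j)] + w
  }
  C
}

#' Gaussian-smooth a volume
#'
#' Separable Gaussian convolution with sigma = fwhm / (2 * sqrt(2 * log(2)))
#' per axis, expressed in voxel units via the affine's voxel sizes, so the
#' kernel is isometric in millimetres even on anisotropic grids. Boundaries
#' are reflective, which preserves the total image sum (no edge attenuation
#' of shell signal).
#'
#' @param vol a [ScalarVolume-class].
#' @param fwhmMm full width at half maximum of the kernel, mm (> 0).
#' @return the smoothed [ScalarVolume-class].
#' @export
smoothVolume <- function(vol, fwhmMm) {
  stopifnot(is(vol, "ScalarVolume"))
  if (!is.numeric(fwhmMm) || fwhmMm <= 0)
    stopf("fwhm must be > 0 (got %s)", format(fwhmMm))
  vs <- voxelSize(vol)
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / vs
  a <- vol@data
  shp <- dim(a)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    radius <- max(1L, as.integer(ceiling(4 * s)))
    k <- exp(-((-radius:radius)^2) / (2 * s^2))
    k <- k / sum(k)
    C <- .convMatrix(shp[ax], k, radius)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- array(C %*% matrix(ap, nrow = dp[1]), dim = dp)
    a <- aperm(ap, order(perm))
  }
  scalarVolume(a, affine = vol@affine)
}

#' Voxelwise correlation between subject maps and a covariate
#'
#' Pearson correlation at each voxel between subjects' map values and the
#' covariate, with Fisher-transformed z-scores
#' z = atanh(r) * sqrt(n - 3). A voxel enters the analysis mask when at
#' least `minSubjects` subjects (and never fewer than 4) carry a defined
#' value there and the map values are not constant across subjects; voxels
#' outside the mask carry `NA`, never silent zeros.
#'
#' @param maps list of [ScalarVolume-class], one per subject, on one grid.
#'   `NA` voxels are treated as missing for that subject.
#' @param covariates numeric vector parallel to `maps` (non-constant).
#' @param minSubjects minimum subjects per voxel; defaults to all.
#' @param fdr also compute Benjamini-Hochberg q-values from two-sided
#'   Fisher-z p-values over the mask.
#' @return a [StatMap-class].
#' @export
voxelwiseCorrelation <- function(maps, covariates,
                                 minSubjects = length(maps), fdr = FALSE) {
  n <- length(maps)
  if (n != length(covariates))
    stopf("%d maps but %d covariate values", n, length(covariates))
  if (n < 4L) stopf("at least 4 subjects are required (got %d)", n)
  if (stats::sd(covariates) == 0) stopf("constant covariate")
  shp <- dim(maps[[1]]@data)
  aff <- maps[[1]]@affine
  for (m in maps)
    if (!identical(dim(m@data), shp) || max(abs(m@affine - aff)) > 1e-6)
      stopf("subject maps are not on one grid")
  X <- vapply(maps, function(m) as.vector(m@data), numeric(prod(shp)))
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0
  nv <- rowSums(M)
  sC <- as.vector(M %*% covariates)
  sC2 <- as.vector(M %*% covariates^2)
  sX <- rowSums(X0)
  sX2 <- rowSums(X0^2)
  sXC <- as.vector(X0 %*% covariates)
  varX <- nv * sX2 - sX^2
  varC <- nv * sC2 - sC^2
  mask <- nv >= max(minSubjects, 4L) & varX > 1e-24 & varC > 1e-24
  r <- rep(NA_real_, length(mask))
  r[mask] <- (nv[mask] * sXC[mask] - sX[mask] * sC[mask]) /
    sqrt(varX[mask] * varC[mask])
  r[mask] <- pmin(1, pmax(-1, r[mask]))
  z <- rep(NA_real_, length(mask))
  rc <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r[mask]))
  z[mask] <- atanh(rc) * sqrt(nv[mask] - 3)
  q <- rep(NA_real_, length(mask))
  if (fdr) {
    p <- 2 * stats::pnorm(-abs(z[mask]))
    q[mask] <- stats::p.adjust(p, method = "BH")
  }
  new("StatMap",
      r = array(r, dim = shp), z = array(z, dim = shp),
      q = array(q, dim = shp),
      nPerVoxel = array(as.integer(nv), dim = shp),
      mask = array(as.integer(mask), dim = shp),
      threshold = NA_real_, affine = aff)
}

#' Threshold a statistical map
#'
#' One-sided cutoff on the z map, restricted to the analysis mask.
#'
#' @param stat a [StatMap-class].
#' @param zCut z cutoff.
#' @param direction `"less_than"` keeps z < zCut, `"greater_than"` keeps
#'   z > zCut.
#' @return a binary [LabelVolume-class] of voxels passing the cutoff.
#' @export
thresholdMap <- function(stat, zCut, direction = c("less_than",
                                                   "greater_than")) {
  stopifnot(is(stat, "StatMap"))
  direction <- match.arg(direction)
  pass <- stat@mask > 0 & !is.na(stat@z) &
    (if (direction == "less_than") stat@z < zCut else stat@z > zCut)
  labelVolume(array(as.integer(pass), dim = dim(stat@z)),
              affine = stat@affine)
}

#' Summarize a thresholded statistical map
#'
#' @param stat a [StatMap-class].
#' @param thresholded binary [LabelVolume-class] from [thresholdMap()].
#' @return one-row data.frame: voxels passing, peak z, peak voxel indices
#'   (0-based) and peak mm coordinates. The peak is the most extreme z among
#'   passing voxels (or in the whole mask when nothing passes).
#' @export
statSummary <- function(stat, thresholded) {
  pass <- thresholded@data > 0
  zSel <- if (any(pass)) stat@z[pass] else stat@z[stat@mask > 0]
  if (!length(zSel) || all(is.na(zSel))) {
    return(data.frame(n_voxels = 0L, peak_z = NA_real_, peak_i = NA_integer_,
                      peak_j = NA_integer_, peak_k = NA_integer_,
                      peak_x_mm = NA_real_, peak_y_mm = NA_real_,
                      peak_z_mm = NA_real_))
  }
  peakVal <- zSel[which.max(abs(zSel))]
  where <- if (any(pass)) which(pass & stat@z == peakVal) else
    which(stat@mask > 0 & stat@z == peakVal)
  pk <- gridIndices(dim(stat@z))[where[1], ]
  mm <- drop(voxelToWorldMm(matrix(pk, 1), stat@affine))
  data.frame(n_voxels = sum(pass), peak_z = peakVal,
             peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
             peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3])
}
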