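#' Unite all gray matter ROIs into one binary mask
#'
#' @param parcellation a [LabelVolume-class] of gray matter ROI labels.
#' @return a binary [LabelVolume-class] (1 where any label, 0 elsewhere) on
#'   the same grid.
#' @export
uniteGrayMask <- function(parcellation) {
  stopifnot(is(parcellation, "LabelVolume"))
  if (!any(parcellation@data > 0L))
    stopf("no gray matter labels in parcellation")
  labelVolume(array(as.integer(parcellation@data > 0L),
                    dim = dim(parcellation@data)),
              affine = parcellation@affine)
}

# Offsets of the six face neighbors.
.faceOffsets <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                      c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))

#' Gray labels touching the six faces of a voxel
#'
#' Returns the gray matter labels (label > 0) of the up-to-six face-adjacent
#' voxels, with multiplicity. Neighbors outside the grid contribute nothing;
#' "contact" is face adjacency only, never edge or corner.
#'
#' @param parcellation a [LabelVolume-class].
#' @param voxel 0-based integer (i, j, k) triple inside the grid.
#' @return integer vector of gray neighbor labels (possibly empty), one entry
#'   per touching face.
#' @export
faceNeighborLabels <- function(parcellation, voxel) {
  stopifnot(is(parcellation, "LabelVolume"))
  shp <- dim(parcellation@data)
  voxel <- as.integer(voxel)
  if (any(voxel < 0L) || any(voxel >= shp))
    stopf("voxel (%s) out of bounds for grid %s",
          paste(voxel, collapse = ", "), paste(shp, collapse = " x "))
  nb <- sweep(.faceOffsets, 2, voxel, "+")
  ok <- nb[, 1] >= 0 & nb[, 1] < shp[1] & nb[, 2] >= 0 & nb[, 2] < shp[2] &
    nb[, 3] >= 0 & nb[, 3] < shp[3]
  labs <- parcellation@data[linearIndex(nb[ok, , drop = FALSE], shp)]
  labs[labs > 0L]
}

# Face-neighbor label matrix for all grid voxels: N x 6, 0 where the neighbor
# is background or off-grid. Built by array shifting, vectorized.
.neighborLabelMatrix <- function(labels) {
  shp <- dim(labels)
  out <- matrix(0L, prod(shp), 6L)
  for (f in seq_len(6L)) {
    off <- .faceOffsets[f, ]
    shifted <- array(0L, dim = shp)
    if (all(shp[off != 0L] >= 2L)) {
      src <- list(seq_len(shp[1]), seq_len(shp[2]), seq_len(shp[3]))
      dst <- src
      for (ax in 1:3) {
        if (off[ax] == 1L) {        # neighbor at +1: shift down
          src[[ax]] <- 2:shp[ax]; dst[[ax]] <- 1:(shp[ax] - 1L)
        } else if (off[ax] == -1L) {
          src[[ax]] <- 1:(shp[ax] - 1L); dst[[ax]] <- 2:shp[ax]
        }
      }
      shifted[dst[[1]], dst[[2]], dst[[3]]] <-
        labels[src[[1]], src[[2]], src[[3]]]
    }
    out[, f] <- as.vector(shifted)
  }
  out
}

#' Build the gray-white matter transition shell
#'
#' A white matter voxel enters the shell when at least one of its six faces
#' touches a gray matter label; it is assigned the label accounting for the
#' majority of its touching faces. Draws between two or more equally
#' represented labels are resolved by a uniform random choice among the tied
#' labels, driven by `seed` so identical seeds reproduce identical shells.
#'
#' @param parcellation gray matter [LabelVolume-class].
#' @param wmMask binary white matter [LabelVolume-class] on the same grid;
#'   gray labels and white mask must be disjoint.
#' @param seed integer tie-breaking seed.
#' @return a [TransitionShell-class].
#' @examples
#' lab <- array(0L, c(4, 4, 4)); lab[1, , ] <- 1L; lab[4, , ] <- 2L
#' wm <- array(0L, c(4, 4, 4)); wm[2:3, , ] <- 1L
#' buildShell(labelVolume(lab), labelVolume(wm), seed = 1)
#' @export
buildShell <- function(parcellation, wmMask, seed = 0L) {
  stopifnot(is(parcellation, "LabelVolume"), is(wmMask, "LabelVolume"))
  shp <- dim(parcellation@data)
  if (!identical(shp, dim(wmMask@data)) ||
      max(abs(parcellation@affine - wmMask@affine)) > 1e-8)
    stopf("grid mismatch between parcellation and white matter mask")
  if (!all(wmMask@data %in% c(0L, 1L)))
    stopf("white matter mask must be binary")
  overlap <- which(wmMask@data == 1L & parcellation@data > 0L)
  if (length(overlap)) {
    v <- gridIndices(shp)[overlap[1], ]
    stopf("gray label and white mask overlap at voxel (%s)",
          paste(v, collapse = ", "))
  }
  nb <- .neighborLabelMatrix(parcellation@data)
  wm <- as.vector(wmMask@data) == 1L
  contact <- rowSums(nb > 0L) > 0L
  sel <- which(wm & contact)
  if (!length(sel)) {
    return(new("TransitionShell",
               voxels = matrix(integer(), 0, 3), labels = integer(),
               gridShape = as.integer(shp), affine = parcellation@affine,
               seed = as.integer(seed)))
  }
  nbS <- nb[sel, , drop = FALSE]
  labs <- sort(unique(as.vector(nbS)))
  labs <- labs[labs > 0L]
  votes <- vapply(labs, function(u) rowSums(nbS == u), numeric(length(sel)))
  votes <- matrix(votes, nrow = length(sel))
  assigned <- withSeed(seed,
    labs[max.col(votes, ties.method = "random")])
  new("TransitionShell",
      voxels = gridIndices(shp)[sel, , drop = FALSE],
      labels = as.integer(assigned), gridShape = as.integer(shp),
      affine = parcellation@affine, seed = as.integer(seed))
}

#' Serialize a transition shell as a label volume
#'
#' @param shell a [TransitionShell-class].
#' @return a [LabelVolume-class] with the ROI assignment at shell voxels and
#'   0 elsewhere.
#' @export
shellToLabelVolume <- function(shell) {
  stopifnot(is(shell, "TransitionShell"))
  out <- array(0L, dim = shell@gridShape)
  if (nrow(shell@voxels))
    out[linearIndex(shell@voxels, shell@gridShape)] <- shell@labels
  labelVolume(out, affine = shell@affine)
}

#' Rebuild a transition shell from its label-volume serialization
#'
#' @param vol a [LabelVolume-class] as produced by [shellToLabelVolume()].
#' @param seed tie seed to record on the rebuilt shell.
#' @return a [TransitionShell-class] with the same voxel set and labels.
#' @export
shellFromLabelVolume <- function(vol, seed = 0L) {
  stopifnot(is(vol, "LabelVolume"))
  sel <- which(vol@data > 0L)
  new("TransitionShell",
      voxels = gridIndices(dim(vol@data))[sel, , drop = FALSE],
      labels = as.integer(vol@data[sel]),
      gridShape = as.integer(dim(vol@data)), affine = vol@affine,
      seed = as.integer(seed))
}

#' Write a shell as a plain-text voxel table
#'
#' Four tab-separated columns of 0-based indices and the assigned label,
#' preceded by the header line `# i j k label`.
#'
#' @param shell a [TransitionShell-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeShellTable <- function(shell, path) {
  stopifnot(is(shell, "TransitionShell"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# i j k label", con)
  if (nrow(shell@voxels)) {
    tab <- cbind(shell@voxels, shell@labels)
    writeLines(apply(tab, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a shell voxel table written by [writeShellTable()]
#' @param path table path.
#' @param gridShape integer triple of the grid the shell lives on.
#' @param affine 4x4 voxel-to-world transform of that grid.
#' @param seed tie seed to record.
#' @return a [TransitionShell-class].
#' @export
readShellTable <- function(path, gridShape, affine = diag(4), seed = 0L) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("i", "j", "k", "label"))
  new("TransitionShell",
      voxels = as.matrix(tab[, 1:3]), labels = as.integer(tab$label),
      gridShape = as.integer(gridShape), affine = affine,
      seed = as.integer(seed))
}
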