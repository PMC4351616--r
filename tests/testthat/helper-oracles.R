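# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-voxel loops, direct formulas) so they cannot share
# defects with the vectorized implementation they check.

# Brute-force shell: loop every white voxel, inspect its 6 faces directly.
# Returns 0-based voxel rows, the face-label multiset per voxel, and the
# strict-majority label (NA when tied).
oracleShell <- function(labels, wm) {
  shp <- dim(labels)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  vox <- list(); faces <- list(); major <- integer()
  for (w in which(wm == 1L)) {
    ijk <- arrayInd(w, shp)
    labs <- integer()
    for (f in 1:6) {
      nb <- ijk + offs[f, ]
      if (all(nb >= 1) && all(nb <= shp)) {
        l <- labels[nb[1], nb[2], nb[3]]
        if (l > 0) labs <- c(labs, l)
      }
    }
    if (length(labs)) {
      vox[[length(vox) + 1L]] <- ijk - 1L
      faces[[length(faces) + 1L]] <- labs
      tab <- table(labs)
      top <- as.integer(names(tab)[tab == max(tab)])
      major <- c(major, if (length(top) == 1L) top else NA_integer_)
    }
  }
  list(voxels = do.call(rbind, c(vox, list(matrix(integer(), 0, 3)))),
       faces = faces, majority = major)
}

# Naive adjacency-excluded count: per shell voxel, loop over all maps.
oracleSumNonlocal <- function(shell, maps) {
  shp <- shell@gridShape
  out <- array(0, dim = shp)
  v <- shellVoxels(shell); lab <- shellLabels(shell)
  for (i in seq_len(nrow(v))) {
    s <- 0
    for (m in maps) {
      if (m@seedRoi != lab[i])
        s <- s + m@counts[v[i, 1] + 1, v[i, 2] + 1, v[i, 3] + 1]
    }
    out[v[i, 1] + 1, v[i, 2] + 1, v[i, 3] + 1] <- s
  }
  out
}

# Random smooth-ish parcellation + white mask on a cube: gray = balls around
# k random centers, white = a band around the gray, everything disjoint.
randomParcellation <- function(seed, shape = c(20L, 20L, 20L), k = 3L,
                               grayRadius = 3.5, whiteRadius = 7) {
  set.seed(seed)
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  centers <- cbind(runif(k, 4, shape[1] - 5), runif(k, 4, shape[2] - 5),
                   runif(k, 4, shape[3] - 5))
  d <- sapply(seq_len(k), function(c)
    sqrt(rowSums(sweep(idx, 2, centers[c, ])^2)))
  d <- matrix(d, ncol = k)
  nearest <- max.col(-d)
  dmin <- d[cbind(seq_len(nrow(d)), nearest)]
  lab <- ifelse(dmin <= grayRadius, nearest, 0L)
  wm <- as.integer(dmin > grayRadius & dmin <= whiteRadius)
  list(parcellation = labelVolume(array(as.integer(lab), dim = shape)),
       wmMask = labelVolume(array(wm, dim = shape)))
}

# A four-voxel-thick slab phantom: ROI 1 at x = 0, ROI 2 at x = 3, white in
# between — the canonical exhaustively-checkable shell example.
slabPhantom <- function() {
  lab <- array(0L, c(4, 4, 4)); lab[1, , ] <- 1L; lab[4, , ] <- 2L
  wm <- array(0L, c(4, 4, 4)); wm[2:3, , ] <- 1L
  list(parcellation = labelVolume(lab), wmMask = labelVolume(wm))
}

# Uniform +x direction field on a box grid with full inclusion mask.
uniformField <- function(shape = c(40L, 8L, 8L), dir = c(1, 0, 0)) {
  vecs <- array(0, dim = c(shape, 3))
  for (ax in 1:3) vecs[, , , ax] <- dir[ax] / sqrt(sum(dir^2))
  directionField(vecs, array(1L, dim = shape))
}

# A visitation map with given counts and integer-count provenance.
countMap <- function(roi, counts, affine = diag(4)) {
  new("VisitationMap", seedRoi = as.integer(roi),
      counts = array(as.double(counts), dim = dim(counts)), affine = affine,
      params = trackingParams(distanceCorrection = FALSE))
}

# 0-based (i, j, k) rows -> 1-based linear indices for an array of `shape`.
linIdx0 <- function(idx, shape) {
  1L + idx[, 1] + shape[1] * (idx[, 2] + shape[2] * idx[, 3])
}
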