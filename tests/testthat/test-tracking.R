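test_that("tracking defaults match the standard probabilistic settings", {
  p <- trackingParams()
  expect_identical(p@nSamples, 5000L)
  expect_equal(p@curvatureThreshold, 0.2)
  expect_identical(p@maxSteps, 200L)
  expect_equal(p@stepLengthMm, 0.5)
  expect_true(p@distanceCorrection)
  f <- withr::local_tempfile(fileext = ".txt")
  writeTrackingParams(p, f)
  back <- readTrackingParams(f)
  expect_equal(back, p)
})

test_that("a uniform field yields a straight path of exactly maxSteps steps", {
  fld <- uniformField(c(60, 5, 5))
  p <- trackingParams(maxSteps = 100L, dispersionDeg = 0, seed = 1)
  path <- propagateStreamline(fld, c(2, 2, 2), p)
  expect_equal(nrow(path), 101L)
  steps <- diff(path)
  expect_true(all(abs(sqrt(rowSums(steps^2)) - 0.5) < 1e-12))
  expect_true(all(abs(steps[, 2:3]) < 1e-12))   # never leaves the x axis
})

test_that("the curvature gate stops bends; sign alignment absorbs reversals", {
  # direction data are axes, not vectors: a sign flip at a plane is aligned
  # away and the streamline crosses it
  shape <- c(20L, 5L, 5L)
  vecs <- array(0, dim = c(shape, 3))
  vecs[1:10, , , 1] <- 1
  vecs[11:20, , , 1] <- -1
  fld <- directionField(vecs, array(1L, dim = shape))
  p <- trackingParams(dispersionDeg = 0, seed = 1)
  path <- propagateStreamline(fld, c(2, 2, 2), p)
  expect_true(max(path[, 1]) > 10)

  # a genuine 90-degree bend has step cosine 0 < 0.2 and terminates there
  vecs2 <- array(0, dim = c(shape, 3))
  vecs2[1:10, , , 1] <- 1
  vecs2[11:20, , , 2] <- 1
  fld2 <- directionField(vecs2, array(1L, dim = shape))
  path2 <- propagateStreamline(fld2, c(2, 2, 2), p)
  expect_lt(max(path2[, 1]), 11)    # never proceeds past the bend
  expect_true(all(abs(path2[, 2] - 2) < 1e-12))
})

test_that("termination: mask exit, zero-vector voxel, and step budget", {
  # start one step from the mask edge -> path of <= 2 points
  fld <- uniformField(c(6, 3, 3))
  p <- trackingParams(dispersionDeg = 0, seed = 1)
  path <- propagateStreamline(fld, c(5, 1, 1), p)
  expect_lte(nrow(path), 2L)

  # zero-vector voxel ends the path
  shape <- c(12L, 3L, 3L)
  vecs <- array(0, dim = c(shape, 3))
  vecs[1:6, , , 1] <- 1
  fldz <- directionField(vecs, array(1L, dim = shape))
  pz <- propagateStreamline(fldz, c(1, 1, 1), p)
  expect_lt(max(pz[, 1]), 7.1)

  # step budget caps the path length
  fldLong <- uniformField(c(200, 3, 3))
  p2 <- trackingParams(maxSteps = 17L, dispersionDeg = 0, seed = 1)
  expect_equal(nrow(propagateStreamline(fldLong, c(1, 1, 1), p2)), 18L)

  expect_error(propagateStreamline(fld, c(50, 1, 1), p), "inclusion mask")
})

test_that("realized step cosines never fall below the curvature threshold", {
  fld <- uniformField(c(40, 20, 20))
  p <- trackingParams(dispersionDeg = 25, curvatureThreshold = 0.2,
                      maxSteps = 60L, seed = 4)
  withr::with_seed(4, {
    for (rep in 1:20) {
      path <- propagateStreamline(fld, c(5, 10, 10), p)
      if (nrow(path) >= 3) {
        d <- diff(path)
        d <- d / sqrt(rowSums(d^2))
        cosines <- rowSums(d[-nrow(d), , drop = FALSE] *
                           d[-1, , drop = FALSE])
        expect_gte(min(cosines), 0.2 - 1e-9)
      }
      # step length is exact even under jitter
      expect_true(all(abs(sqrt(rowSums(diff(path)^2)) - 0.5) < 1e-9))
    }
  })
})

test_that("seed-voxel tracking produces exact counts on a straight bundle", {
  ph <- makePhantom(phantomSpec())
  shell <- buildShell(ph$parcellation, ph$wmMask, seed = 0)
  p <- trackingParams(nSamples = 25L, distanceCorrection = FALSE,
                      dispersionDeg = 0, seed = 3)
  m <- seedRoiTracking(ph$field, shell, 2L, p)
  counts <- rawCounts(m)
  # the single bundle column from ROI 2's entry voxel carries n_samples
  expect_equal(max(counts), 25)
  bundleCol <- counts[, 6, 6]
  expect_true(any(bundleCol == 25))
  # off-field shell seeds visit only themselves: every count is 0 or 25
  expect_true(all(counts %in% c(0, 25)))
  # counting bound: k seed voxels x n samples
  k <- sum(shellLabels(shell) == 2L)
  expect_lte(max(counts), k * 25)
  # determinism
  m2 <- seedRoiTracking(ph$field, shell, 2L, p)
  expect_identical(rawCounts(m2), counts)
  expect_error(seedRoiTracking(ph$field, shell, 99L, p), "absent")
})

test_that("distance correction weights visits by path length at first visit", {
  fld <- uniformField(c(30, 3, 3))
  lab <- array(0L, c(30, 3, 3)); lab[1, , ] <- 1L
  wm <- array(0L, c(30, 3, 3)); wm[2:30, , ] <- 1L
  shell <- buildShell(labelVolume(lab), labelVolume(wm), seed = 0)
  one <- shellVoxels(shell)[shellLabels(shell) == 1L, , drop = FALSE]
  p <- trackingParams(nSamples = 4L, distanceCorrection = TRUE,
                      dispersionDeg = 0, maxSteps = 10L, bidirectional = FALSE,
                      seed = 1)
  m <- seedRoiTracking(fld, shell, 1L, p)
  counts <- rawCounts(m)
  seedV <- one[one[, 2] == 1 & one[, 3] == 1, ]
  # voxel at distance d is first entered at position d - 0.5 mm
  expect_equal(counts[seedV[1] + 1, 2, 2], 0)          # length 0 at the seed
  expect_equal(counts[seedV[1] + 2, 2, 2], 4 * 0.5)
  expect_equal(counts[seedV[1] + 3, 2, 2], 4 * 1.5)

  pInt <- trackingParams(nSamples = 4L, distanceCorrection = FALSE,
                         dispersionDeg = 0, maxSteps = 10L, seed = 1)
  mInt <- seedRoiTracking(fld, shell, 1L, pInt)
  expect_true(all(rawCounts(mInt) == round(rawCounts(mInt))))
})

test_that("visitation map loading validates grids, lengths and signs", {
  d <- withr::local_tempdir()
  aff <- diag(4)
  for (k in 1:3)
    writeVolume(scalarVolume(array(k * 1.0, c(4, 4, 4)), aff),
                file.path(d, sprintf("seed_%d_paths.nii.gz", k)))
  maps <- loadVisitationMaps(file.path(d, sprintf("seed_%d_paths.nii.gz", 1:3)),
                             1:3)
  expect_length(maps, 3L)
  expect_identical(vapply(maps, function(m) m@seedRoi, integer(1)), 1:3)

  expect_error(loadVisitationMaps(file.path(d, "seed_1_paths.nii.gz"), 1:2),
               "1 paths but 2")
  writeVolume(scalarVolume(array(0, c(5, 5, 5)), aff),
              file.path(d, "seed_4_paths.nii.gz"))
  expect_error(
    loadVisitationMaps(file.path(d, sprintf("seed_%d_paths.nii.gz", c(1, 4))),
                       c(1, 4)), "grid mismatch")
  neg <- array(0, c(4, 4, 4)); neg[1] <- -1
  writeVolume(scalarVolume(neg, aff), file.path(d, "seed_5_paths.nii.gz"))
  expect_error(loadVisitationMaps(file.path(d, "seed_5_paths.nii.gz"), 5),
               "negative count")
})

test_that("monte-carlo visitation mass stabilizes as samples grow", {
  fld <- uniformField(c(24, 9, 9))
  lab <- array(0L, c(24, 9, 9)); lab[1, 4:6, 4:6] <- 1L
  wm <- array(0L, c(24, 9, 9)); wm[2:24, , ] <- 1L
  shell <- buildShell(labelVolume(lab), labelVolume(wm), seed = 0)
  massPerSample <- function(n, seed) {
    p <- trackingParams(nSamples = n, distanceCorrection = FALSE,
                        dispersionDeg = 20, maxSteps = 20L,
                        bidirectional = FALSE, seed = seed)
    sum(rawCounts(seedRoiTracking(fld, shell, 1L, p))) / n
  }
  small <- vapply(1:6, function(s) massPerSample(5L, s), numeric(1))
  large <- vapply(1:6, function(s) massPerSample(80L, s), numeric(1))
  expect_lt(sd(large), sd(small))   # standard error shrinks with n
})
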