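# A tiny 3-ROI shell on a 4x4x4 grid with hand-set visitation counts.
tinyShellFixture <- function() {
  lab <- array(0L, c(4, 4, 4))
  lab[1, , ] <- 1L; lab[4, 1:2, ] <- 2L; lab[4, 3:4, ] <- 3L
  wm <- array(0L, c(4, 4, 4)); wm[2:3, , ] <- 1L
  shell <- buildShell(labelVolume(lab), labelVolume(wm), seed = 0)
  list(shell = shell, gridShape = c(4L, 4L, 4L))
}

test_that("nonlocal summation excludes the voxel's own ROI", {
  fx <- tinyShellFixture()
  shp <- fx$gridShape
  # per-map constant counts 5, 2, 7 everywhere
  maps <- list(countMap(1, array(5, shp)), countMap(2, array(2, shp)),
               countMap(3, array(7, shp)))
  f <- sumNonlocalCounts(fx$shell, maps)
  v <- shellVoxels(fx$shell); lab <- shellLabels(fx$shell)
  lin <- v[, 1] + 1 + 4 * (v[, 2] + 4 * v[, 3])
  fv <- volData(f)[lin]
  expect_true(all(fv[lab == 1L] == 2 + 7))   # 9: excludes its own 5
  expect_true(all(fv[lab == 2L] == 5 + 7))
  expect_true(all(fv[lab == 3L] == 5 + 2))
  expect_true(all(volData(f)[-lin] == 0))    # zero off the shell

  # visits only from the voxel's own ROI -> f = 0 there
  own <- list(countMap(1, array(9, shp)), countMap(2, array(0, shp)),
              countMap(3, array(0, shp)))
  f0 <- sumNonlocalCounts(fx$shell, own)
  expect_true(all(volData(f0)[lin[lab == 1L]] == 0))

  zero <- lapply(1:3, function(k) countMap(k, array(0, shp)))
  expect_true(all(volData(sumNonlocalCounts(fx$shell, zero)) == 0))

  expect_error(sumNonlocalCounts(fx$shell, maps[1:2]),
               "no visitation map for shell ROI 3")
  badGrid <- list(countMap(1, array(0, c(5, 5, 5))), maps[[2]], maps[[3]])
  expect_error(sumNonlocalCounts(fx$shell, badGrid), "grid mismatch")
})

test_that("nonlocal summation matches the naive per-voxel oracle", {
  for (s in 1:5) {
    rp <- randomParcellation(s, shape = c(12L, 12L, 12L), k = 4L)
    shell <- buildShell(rp$parcellation, rp$wmMask, seed = s)
    rois <- sort(unique(shellLabels(shell)))
    set.seed(s + 100)
    maps <- lapply(rois, function(k)
      countMap(k, array(rpois(12^3, 3), c(12, 12, 12))))
    fast <- volData(sumNonlocalCounts(shell, maps))
    expect_equal(fast, oracleSumNonlocal(shell, maps))
  }
})

test_that("the log transform is log(f + 1) and rejects negatives", {
  f <- scalarVolume(array(c(0, exp(1) - 1, 3, 7), c(4, 1, 1)))
  fp <- logTransform(f)
  expect_equal(volData(fp)[1, 1, 1], 0)
  expect_equal(volData(fp)[2, 1, 1], 1)
  expect_equal(volData(fp), log1p(volData(f)))
  expect_true(all(diff(as.vector(volData(fp))[c(1, 3, 4)]) > 0))
  expect_error(logTransform(scalarVolume(array(-1, c(2, 1, 1)))), "negative")
})

test_that("min-max normalization follows the printed formula exactly", {
  # shell of 5 voxels along x=1 with counts 1, 2, 10, 0, 2
  lab <- array(0L, c(3, 5, 1)); lab[1, , ] <- 1L
  lab2 <- array(0L, c(3, 5, 1)); lab2[3, , ] <- 2L
  lab[lab2 == 2L] <- 2L
  wm <- array(0L, c(3, 5, 1)); wm[2, , ] <- 1L
  shell <- buildShell(labelVolume(lab), labelVolume(wm), seed = 0)
  counts <- array(0, c(3, 5, 1))
  counts[2, , 1] <- c(1, 2, 10, 0, 2)
  f <- scalarVolume(counts)
  g <- normalizeWithinSubject(logTransform(f), shell, f)
  expect_equal(unname(normalizationRange(g)), c(log(2), log(11)))
  Fm <- normalizedMap(g)
  expect_equal(Fm[2, 2, 1], (log(3) - log(2)) / (log(11) - log(2)))
  expect_equal(Fm[2, 3, 1], 1)          # attains the maximum
  expect_equal(Fm[2, 1, 1], 0)          # attains the minimum
  expect_equal(Fm[2, 4, 1], 0)          # f = 0: flagged, F = 0
  expect_equal(g@zeroMask[2, 4, 1], 1L)
  expect_equal(g@zeroMask[2, 1, 1], 0L) # minimum is NOT the zero flag
  expect_equal(Fm[2, 5, 1], Fm[2, 2, 1])  # equal f -> equal F
})

test_that("normalization degenerate cases behave as documented", {
  lab <- array(0L, c(3, 3, 1)); lab[1, , ] <- 1L
  wm <- array(0L, c(3, 3, 1)); wm[2, , ] <- 1L
  shell <- buildShell(labelVolume(lab), labelVolume(wm), seed = 0)
  allZero <- scalarVolume(array(0, c(3, 3, 1)))
  expect_error(normalizeWithinSubject(logTransform(allZero), shell, allZero),
               "no connectivity signal")
  eq <- array(0, c(3, 3, 1)); eq[2, , 1] <- 4
  eqv <- scalarVolume(eq)
  expect_warning(g <- normalizeWithinSubject(logTransform(eqv), shell, eqv),
                 "degenerate normalization range")
  expect_true(all(normalizedMap(g)[2, , 1] == 1))
})

test_that("F is monotone in f and invariant to log base and count rescaling", {
  lab <- array(0L, c(3, 8, 1)); lab[1, , ] <- 1L
  wm <- array(0L, c(3, 8, 1)); wm[2, , ] <- 1L
  shell <- buildShell(labelVolume(lab), labelVolume(wm), seed = 0)
  set.seed(8)
  counts <- array(0, c(3, 8, 1))
  counts[2, , 1] <- sample(0:50, 8)
  f <- scalarVolume(counts)
  g <- normalizeWithinSubject(logTransform(f), shell, f)
  Fv <- normalizedMap(g)[2, , 1]
  fv <- counts[2, , 1]
  ord <- order(fv)
  expect_true(all(diff(Fv[ord]) >= -1e-12))          # monotone in f

  # base-10 log gives the same F: base change cancels in the ratio
  nz <- fv >= 1
  f10 <- log10(fv + 1)
  F10 <- (f10 - min(f10[nz])) / (max(f10[nz]) - min(f10[nz]))
  expect_equal(Fv[nz], F10[nz], tolerance = 1e-12)

  # rescaling counts preserves the ranking of voxels exactly
  fScaled <- scalarVolume(counts * 7)
  g2 <- normalizeWithinSubject(logTransform(fScaled), shell, fScaled)
  F2 <- normalizedMap(g2)[2, , 1]
  expect_equal(cor(Fv[nz], F2[nz], method = "spearman"), 1)
})

test_that("standard-space resampling composes the two affines once", {
  lab <- array(0L, c(6, 6, 6)); lab[2, , ] <- 1L; lab[5, , ] <- 2L
  wm <- array(0L, c(6, 6, 6)); wm[3:4, , ] <- 1L
  shell <- buildShell(labelVolume(lab), labelVolume(wm), seed = 0)
  set.seed(31)
  counts <- array(0, c(6, 6, 6))
  lin <- linIdx <- shellVoxels(shell)
  counts[cbind(lin[, 1] + 1, lin[, 2] + 1, lin[, 3] + 1)] <-
    sample(1:20, nrow(lin), TRUE)
  f <- scalarVolume(counts)
  g <- normalizeWithinSubject(logTransform(f), shell, f)

  idn <- affineTransform()
  same <- gmacToStandardSpace(g, idn, idn, c(6L, 6L, 6L), diag(4))
  expect_equal(volData(same), normalizedMap(g))

  m1 <- diag(4); m1[1:3, 4] <- c(0.3, -0.2, 0.1)
  m2 <- diag(4); m2[1:3, 4] <- c(-0.1, 0.25, 0.15)
  # on a spatially smooth map the double-interpolation error is small, so
  # composed-once and sequential resampling must agree closely
  gSmooth <- g
  xs <- (0:5) / 5
  gSmooth@normalized <- array(
    outer(outer(xs, xs, function(a, b) 0.4 * a + 0.2 * b), 0.3 * xs, `+`),
    c(6, 6, 6))
  comp <- gmacToStandardSpace(gSmooth, affineTransform(m1),
                              affineTransform(m2), c(6L, 6L, 6L), diag(4))
  twoStep <- resampleScalar(
    resampleScalar(scalarVolume(gSmooth@normalized), affineTransform(m1),
                   c(6L, 6L, 6L), diag(4)),
    affineTransform(m2), c(6L, 6L, 6L), diag(4))
  # compare away from the out-of-field rim
  inner <- as.vector(array(seq_len(216), c(6, 6, 6))[2:5, 2:5, 2:5])
  expect_lt(max(abs(volData(comp)[inner] - volData(twoStep)[inner])), 0.02)
  expect_true(all(volData(comp) >= 0))

  zeroG <- g
  zeroG@normalized[] <- 0
  expect_true(all(volData(gmacToStandardSpace(zeroG, affineTransform(m1),
                                              affineTransform(m2),
                                              c(6L, 6L, 6L),
                                              diag(4))) == 0))

  singXfm <- new("AffineTransform", matrix = diag(4), sourceSpace = "a",
                 targetSpace = "b")
  singXfm@matrix[1, 1] <- 1e-20
  expect_error(gmacToStandardSpace(g, singXfm, affineTransform(),
                                   c(6L, 6L, 6L), diag(4)), "singular")
})

test_that("GMAC output files round-trip raw and normalized volumes", {
  fx <- tinyShellFixture()
  maps <- list(countMap(1, array(5, fx$gridShape)),
               countMap(2, array(2, fx$gridShape)),
               countMap(3, array(7, fx$gridShape)))
  g <- computeGMAC(fx$shell, maps)
  d <- withr::local_tempdir()
  paths <- writeGMAC(g, file.path(d, "subj"))
  expect_equal(volData(readScalarVolume(paths["raw"])), g@raw)
  expect_equal(volData(readScalarVolume(paths["normalized"])), g@normalized)
  side <- readFlatConfig(paths["sidecar"])
  expect_equal(as.numeric(side$f_prime_min), g@fPrimeMin)
  expect_equal(as.numeric(side$f_prime_max), g@fPrimeMax)
})
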