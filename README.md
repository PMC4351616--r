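# gmacmap

Gray matter axonal connectivity maps (GMAC) from diffusion tractography, in
R.

Connectome studies summarize white matter connectivity between pairs of
atlas-defined gray matter regions, which makes every result hostage to the
parcellation. A GMAC sidesteps that: it is a voxel-based map, defined on the
one-voxel **gray–white matter transition shell**, of how many tractography
streamlines traverse each shell voxel when *all other* regions are seeded.
Each shell voxel gets a scalar connectivity value; the resulting volume is
compatible with ordinary voxel-based statistics (smoothing, voxelwise
correlation, thresholded z-maps), for neuroimaging researchers studying
regional cortical connectivity without committing to region boundaries.

## Method core

For a white matter voxel included in the shell (≥ 1 of its 6 faces touches
gray matter, assigned by face-majority vote, random tie-break with a
recorded seed) and assigned to region *k*:

    f  = Σ_{j ≠ k} c_j(v)          adjacency-excluded streamline count
    f' = log(f + 1)
    F  = (f' − f'min) / (f'max − f'min)

where `c_j` is the visitation count volume obtained when region *j* is
seeded, and `f'min`, `f'max` are the subject's minimal and maximal nonzero
log-transformed shell values. `F` lies in [0, 1]; voxels with `f = 0` get
`F = 0` plus a zero-count flag. Group analysis smooths each subject's map
(Gaussian, FWHM in mm), computes voxelwise Pearson correlation with a
covariate, and reports Fisher z-scores `z = atanh(r)·√(n − 3)` with
one-sided thresholds.

The package also ships a simplified probabilistic streamline propagator
(principal-direction field + Gaussian angular jitter; 5000 samples/seed
voxel, 0.5 mm steps, 200 max steps, curvature threshold 0.2, distance
correction — the standard defaults) and phantom/cohort generators so the
entire pipeline runs and is testable without MRI data. External tractography
count volumes (`seed_<label>_paths.nii.gz`) can be used instead of the
built-in tracker.

## Worked example

A two-ROI phantom: two spherical gray regions joined by a single straight
fiber bundle, tracked with 100 streamlines per seed voxel.

```r
library(gmacmap)

ph     <- makePhantom(phantomSpec())            # 24³ grid, 2 ROIs, 1 bundle
shell  <- buildShell(ph$parcellation, ph$wmMask, seed = 1)
shell
#> TransitionShell: 268 voxel(s), 2 ROI(s), grid 24 x 24 x 24 (tie seed 1)

params <- trackingParams(nSamples = 100, distanceCorrection = FALSE, seed = 1)
maps   <- lapply(1:2, function(k) seedRoiTracking(ph$field, shell, k, params))
gmac   <- computeGMAC(shell, maps)
#> Warning: degenerate normalization range: all nonzero counts equal;
#> assigning F = 1 at nonzero voxels
gmac
#> GMACVolume on a 268-voxel shell: 2 voxel(s) with signal, f' range [4.615, 4.615]

which(normalizedMap(gmac) > 0)
#> [1] 3010 3011
gmac@raw[normalizedMap(gmac) > 0]
#> [1] 100 100
```

Reading the output: the shell wraps both gray blobs (268 voxels), but only
the two voxels where the bundle pierces it — the bundle's entry and exit,
linear indices 3010/3011, i.e. voxels (9,5,5) and (10,5,5) — carry signal.
Each received exactly `nSamples = 100` visits from the *other* region's
seeding (own-region streamlines are excluded by construction), giving
`f = 100` and `f' = log(101) ≈ 4.615` at both. Because the idealized bundle
gives every visited voxel an identical count, the min–max range collapses
and both voxels receive `F = 1` (hence the warning, expected on this
phantom). Cohort-level analysis continues with `makeCohort()`,
`smoothVolume()`, `voxelwiseCorrelation()` and `thresholdMap()`.

A command-line front end wrapping the same functions is installed at
`system.file("cli", "gmac.R", package = "gmacmap")` with subcommands
`build-shell`, `track`, `compute`, `stats` and `phantom`; volumes are
NIfTI-1, affines are 4-line whitespace-delimited text matrices (row-major,
source→target mm), tables are TSV, configs are flat `key = value` text.

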