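---
title: "Gray matter axonal connectivity maps: model and methods"
author: "gmacmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray matter axonal connectivity maps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement

Structural connectome analyses summarize white matter connectivity between
pairs of pre-defined gray matter regions, which ties every downstream result
to the choice of parcellation atlas. A gray matter axonal connectivity map
(GMAC) instead assigns a single voxel-based connectivity value to each voxel
of the gray–white matter *transition shell* — the one-voxel layer of white
matter in face contact with gray matter — by counting all tractography
streamlines that traverse that voxel when every *other* region is seeded.
The result is a scalar volume, compatible with ordinary voxel-based
statistics, that measures how much axonal traffic enters or exits the
adjacent cortex without asserting where it comes from or goes to.

The pipeline in this package has four stages, each an exported function
family:

1. **Shell construction** (`buildShell`): a white matter voxel joins the
   shell when at least one of its six faces touches a gray matter label;
   it is assigned the label holding the majority of its touching faces.
   Contact is strictly face adjacency (6-connectivity) — edge and corner
   contact never count. Draws among two or more equally represented labels
   are resolved by a uniform random choice among the tied labels, driven by
   a recorded seed so any run can be reproduced exactly. Voxels carrying
   both a gray label and white mask membership are rejected as input
   errors: tissue classes must be disjoint.
2. **Visitation counting** (`seedRoiTracking` / `loadVisitationMaps`): one
   count volume per seeded region, each streamline incrementing each voxel
   it visits at most once. Externally computed tractography count volumes
   can be substituted for the built-in propagator at this boundary.
3. **GMAC assembly** (`sumNonlocalCounts`, `logTransform`,
   `normalizeWithinSubject`): at a shell voxel assigned to region $k$,

   $$f = \sum_{j \neq k} c_j(\mathbf{v}), \qquad f' = \log(f + 1), \qquad
     F = \frac{f' - f'_{\min}}{f'_{\max} - f'_{\min}},$$

   where $c_j$ is region $j$'s visitation count volume and $f'_{\min}$,
   $f'_{\max}$ are the subject's minimal and maximal *nonzero*
   log-transformed shell values. Excluding the voxel's own region keeps a
   region's own seeding from inflating its apparent connectivity.
4. **Voxel-based statistics** (`smoothVolume`, `voxelwiseCorrelation`,
   `thresholdMap`): Gaussian smoothing, voxelwise Pearson correlation with
   a subject covariate, Fisher z-scores $z = \operatorname{atanh}(r)\sqrt{n-3}$,
   and one-sided thresholding (e.g. $z < -1$ for age-related decline).

## Normalization conventions

Several conventions are deliberate and tested:

* The log base is immaterial: a base change rescales $f'$ affinely and
  cancels in the min–max ratio, so $F$ is identical under natural or
  base-10 logs (tested as a property).
* $f'_{\min}$ and $f'_{\max}$ are computed over *shell voxels with measured
  signal only* ($f \ge 1$ for integer counts; $f > 0$ for real-valued
  distance-corrected counts). The value field is only defined on the shell,
  so "across the brain" means across all shell voxels.
* Shell voxels with $f = 0$ receive $F = 0$ **and** a flag in a zero-count
  mask. "No measured connectivity" is thereby distinguished from "minimum
  measured connectivity", which also maps to $F = 0$.
* If every nonzero voxel carries the same count, the min–max range
  collapses. Every such voxel then attains the maximum, so all of them
  receive $F = 1$, with a warning. This degenerate case is not academic: it
  is exactly what an idealized single-bundle phantom produces, because with
  zero angular dispersion every visited voxel of a seeding column receives
  exactly `nSamples` visits. The hard error is reserved for the truly
  empty case (no shell voxel with signal).

## The simplified tracker

The package does not re-implement Bayesian fiber-orientation sampling. Its
propagator is a controllable stand-in: a voxelwise principal direction plus
Gaussian angular jitter (`dispersionDeg`), integrated with fixed steps.
Defaults follow standard probabilistic tractography practice: 5000
streamlines per seed voxel, 0.5 mm steps, at most 200 steps, curvature
threshold 0.2, distance correction on.

* The curvature threshold is a *minimum cosine* between successive unit
  step directions; candidate directions below it terminate the streamline.
* Field directions are axes, not vectors: each candidate is sign-aligned
  with the previous step before the curvature test, so a pure sign flip in
  the field is crossed silently while a genuine 90° bend (cosine 0 < 0.2)
  terminates. This is the convention of the standard tracking tools; a
  consequence is that only geometry, jitter, masks and the step budget can
  stop a streamline.
* Termination causes: leaving the inclusion mask, entering a zero-direction
  voxel, failing the curvature test, or exhausting the step budget.
* Seeding is bidirectional by default (both field polarities per sample);
  a streamline's two halves share one visited-voxel set, counted once.
* Distance correction weights each voxel's increment by the streamline's
  path length in mm at first visit (0 at the seed voxel). The exact
  semantics of the external tools' flag are not published; tests use
  integer counts (correction off) wherever exactness matters.
* Whether "samples" are per seed voxel or per region is ambiguous in common
  usage; this package seeds per voxel, matching the dominant tool's
  convention.
* Nearest-voxel lookup uses `floor(x + 0.5)` rather than R's
  round-half-to-even, so half-integer boundary positions resolve
  deterministically.

## Phantoms and synthetic cohorts

`makePhantom` builds the study conditions every test runs under: spherical
gray ROIs (default radius 3 voxels) on a deterministic lattice inside a
24³ brain box, white matter filling the rest of the brain, and straight
cylindrical bundles between ROI centers carrying the bundle-axis direction
(zero field elsewhere). The two-ROI default connects its ROIs with a
single-voxel column, so every downstream expectation — which shell voxels
are entered, how many streamlines visit each voxel — can be written down
exactly.

`makeCohort` plants a known statistical structure on top: each subject's
map is the template phantom's $F$ plus a linear covariate effect at chosen
shell voxels plus Gaussian noise on all shell voxels, clamped to $[0, 1]$.
Defaults emulate a small midlife cohort: 18 subjects, an age covariate
uniform on 30–51 years, slope −0.005 per year at effect voxels, noise SD
0.02. Noise is confined to the shell (background stays zero) so the
analysis mask remains meaningful; the `noiseSd = 0` degenerate cohort is
allowed and reproduces the template exactly. Covariates are drawn uniformly
rather than matching any empirical age distribution — only the sign and
detectability of the planted effect matter for validation.

What these phantoms do *not* emulate: partial-volume mixing at tissue
boundaries, curved and crossing fiber geometry, spatially correlated
scanner noise, and registration error. Passing tests therefore demonstrate
the correctness of the algorithms under controlled geometry, not the
behavior of the pipeline on real MRI — in particular, real data cannot
yield the exact count identities the phantom tests assert.

## Statistical calibration

With $n$ subjects, the null distribution of $z$ is approximately standard
normal for $n \gtrsim 10$. A pre-registered simulation at the cohort's
study conditions (1000 independent null voxels, $n = 18$) shows the
one-sided 5% tail captured within binomial error, and the planted-effect
design above is detected at $z < -1$ at essentially full sensitivity
(Monte-Carlo floor 0.80, observed ≈ 0.99 across cohort seeds). Clamping at
the $[0,1]$ boundary truncates noise at extreme template values; the null
level remains nominal within binomial error at the problem sizes tested,
but users analyzing maps saturated at 0 or 1 should prefer the FDR option
(`fdr = TRUE`, Benjamini–Hochberg over mask voxels) over the purely
descriptive $z$ threshold.

No multiple-comparison correction is applied by default: the package
mirrors the descriptive $z < -1$ display convention of voxel-based
correlation maps. The analysis mask contains voxels with defined values in
at least `minSubjects` subjects (default: all) and nonzero variance;
masked-out voxels carry `NA`, never silent zeros.

## Numerical choices

* Resampling: nearest-neighbor for labels (never invents a label),
  trilinear for scalars (output bounded by input range); out-of-field
  voxels become 0. The two native↔standard affines are composed and
  applied in a single interpolation to avoid compounding smoothing.
* Smoothing: separable Gaussian with $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
  per axis in mm, converted to voxel units, truncated at $4\sigma$,
  half-sample reflective boundaries (preserves the total image sum to
  machine precision, avoiding edge attenuation of shell signal).
* Correlation: $r$ clamped to $\pm(1 - 10^{-15})$ before the Fisher
  transform so $z$ stays finite at perfect correlations.
* Problem sizes in the shipped tests and acceptance script are desk-scale
  by design: 20³ random parcellations, 24³ phantoms, 100 streamlines per
  seed voxel, 10 simulated cohorts of 18 subjects. They were chosen as the
  smallest sizes at which every contract is exercised exhaustively.

## Known limitations

* The shell is one voxel thick by construction; sub-voxel boundary
  geometry and surface-based definitions are out of scope.
* GMAC intentionally discards pairwise (origin–target) information; graph
  metrics cannot be computed from it, and no connectome matrix is built.
* The built-in tracker is a stand-in for validation and phantom work, not
  a replacement for diffusion-model-based tractography on real data.
* Affine estimation (registration) is consumed, never performed: transforms
  are plain-text 4×4 matrix inputs.
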