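Package: gmacmap
Title: Gray Matter Axonal Connectivity Maps from Diffusion Tractography
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes voxel-based gray matter axonal connectivity maps (GMAC)
    from labeled cortical parcellations and probabilistic tractography
    visitation counts. Constructs the one-voxel gray-white matter transition
    shell by face-contact majority voting, sums streamline visitation counts
    over all non-adjacent seed regions at each shell voxel, applies a
    log(f + 1) transform and within-subject min-max normalization, and
    supports voxel-based statistical analysis (Gaussian smoothing, voxelwise
    covariate correlation with Fisher z-scores, thresholded maps) of the
    resulting maps across subjects. Includes a simplified probabilistic
    streamline propagator and synthetic phantom/cohort generators so the whole
    pipeline can be exercised without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
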