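Package: tractsheet
Title: Tract-Specific Analysis of White-Matter Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Skeleton-based analysis of white-matter tracts from diffusion
    tensor MRI. Builds discrete medial-surface models of sheet-like tracts
    delineated by deterministic (FACT) tractography, projects per-subject
    tensor data onto the skeleton by searching along the surface normal up
    to the tract boundary, and performs point-wise linear regression with
    permutation-based suprathreshold cluster inference under family-wise
    error control. Includes a voxel-skeleton comparator implementing
    TBSS-style maximum-FA projection, evaluation metrics (pairwise Dice
    overlap, Bhattacharyya distance between FA distributions, exact
    Wilcoxon signed-rank tests), readers and writers for NIfTI tensor
    volumes, TCK/TRK tractograms and VTK surface meshes, and generators
    for synthetic tensor phantoms and neonatal-style cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
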