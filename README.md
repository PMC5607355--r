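# tractsheet

Tract-specific analysis (TSA) of white-matter diffusion tensor MRI in R.

Many major white-matter tracts — the corpus callosum, the corticospinal
tract, the long association fasciculi — are sheets, not tubes. `tractsheet`
models each tract as a **medial surface**: a triangulated mid-surface
skeleton with a per-vertex unit normal and a radius function *R(v)*, the
radius of the maximal sphere inscribed in the tract boundary and centred at
*v*. Each subject's diffusion data are projected onto this skeleton by
searching along the surface normal from *v* out to the boundary at
*v ± R(v)·n(v)*, and point-wise statistics are computed on the skeleton with
non-parametric cluster-level family-wise error control. The boundary is the
stopping criterion of the projection search, which is what keeps data from
neighbouring tracts out — the key difference from whole-brain voxel-skeleton
methods (TBSS), whose distance-map-limited maximum-FA search can cross into
adjacent structures. The package includes a TBSS-style comparator so that
difference is directly demonstrable.

It is aimed at researchers analysing tract-level microstructure in cohorts —
including neonatal cohorts, where tensor-derived metrics (FA, MD, AD, RD)
change rapidly with post-menstrual age — who want anatomically specific,
point-wise inference without manually delineating every subject.

## What is in the box

| Stage | Functions |
|---|---|
| I/O: NIfTI tensors/scalars/masks, TCK/TRK streamlines, VTK meshes, CSV cohorts | `read_tensor_volume()`, `read_tractogram()`, `write_mesh()`, `read_cohort()`, ... |
| Tensor metrics | `eigensystem()`, `fa()`, `md()`, `ad()`, `rd()`, `metric_volume()`, `mean_tensor()` |
| FACT deterministic tractography + ROI selection | `fact_track()`, `select_streamlines()`, `tract_mask()`, `snr_estimate()` |
| Medial-surface skeleton | `extract_medial_surface()`, `boundary_offsets()`, `coverage_fraction()`, `distance_transform()` |
| Skeleton projection | `project_subject()` (max-FA or mean-tensor strategy) |
| TBSS-style comparator | `fa_skeletonize()`, `tbss_project()`, `label_skeleton_by_tract()` |
| Statistics | `fit_glm()`, `cluster_permutation_test()` (Freedman–Lane permutation, suprathreshold cluster FWER) |
| Evaluation | `dice()`, `pairwise_median_dice()`, `fa_histogram()`, `bhattacharyya_distance()`, `wilcoxon_signed_rank()`, `compare_projection_methods()` |
| Synthetic data | `make_sheet_phantom()`, `make_cohort()` — analytic sheet phantoms and preterm-style cohorts |

A thin command-line front end lives at `inst/cli/tractsheet.R`
(`Rscript tractsheet.R track|skeleton|project|stats|... --key value`); every
subcommand writes a provenance JSON beside its output.

## The statistical model

At each skeleton vertex the projected metric *y* is regressed on the
covariate of interest (e.g. post-menstrual age at scan) with nuisance
covariates (e.g. gestational age at birth):

    y_v = β0 + β1·PMA + β2·GA + ε,   t_v = β̂1 / SE(β̂1)

Clusters are connected components of `{v : t_v > t_primary}` on the surface
graph. Significance is assessed against the permutation null of the maximum
cluster size, permuting nuisance-model residuals (Freedman–Lane), giving
corrected p-values `(1 + #{max_perm ≥ size}) / (1 + n_perm)` with family-wise
error control.

## Worked example

```r
library(tractsheet)

# a curved sheet phantom (2 mm voxels, 5 mm half-thickness) and its skeleton
spec <- sheet_phantom_spec(dims = c(48, 40, 24), voxel_mm = 2,
                           half_thickness_mm = 5, amplitude_mm = 6)
phantom  <- make_sheet_phantom(spec)
skeleton <- extract_medial_surface(phantom$mask, smoothing_mm = 1)
#> <medial_surface> 1880 vertices, 3588 triangles, R in [4.23, 6.00] mm

# project the tensor volume onto the skeleton (max-FA strategy)
fa_map <- project_subject(skeleton, phantom$volume,
                          projection_params("max"), metric = "FA")
#> <skeleton_map FA/max> 1880 vertices, 0 missing     # FA 0.541-0.550

# a 30-subject preterm-style cohort with FA increasing by 0.012/week of
# post-menstrual age on a 50-vertex patch, then cluster inference
cohort <- make_cohort(cohort_spec(n_subjects = 30, beta = 0.012, seed = 1),
                      skeleton)
res <- cluster_permutation_test(cohort$maps, cohort$cohort,
                                design_spec("PMA_scan", "GA_birth", "positive"),
                                surface_adjacency(skeleton),
                                n_perm = 1000, seed = 7)
res
#> <cluster_result> 29 clusters, primary t = 2.473, 1000 permutations
#>    size peak_t corrected_p
#> ...
#> 16   51  8.848     0.00100
#> ...
```

The 51-vertex cluster at corrected p = 0.001 is the planted patch (100 %
overlap); the remaining 1–2-vertex clusters are noise excursions above the
cluster-forming threshold and are correctly non-significant (p ≥ 0.33).

The projected FA of 0.541–0.550 reflects the phantom's design: FA peaks at
0.55 on the mid-surface, and the max-FA strategy picks the tensor nearest
the tract core in every normal search.

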