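# ficdmap

Vertex-wise **fiber connectivity density (FiCD)** mapping of the cortex from
diffusion-tensor data, with a fully synthetic phantom bench so every stage
is testable without MRI data.

FiCD measures how much white-matter connectivity converges on a unit patch
of cortex. The gray–white matter interface is parcellated into K ≈ 2000
approximately equal-area cortical units (CUs); the subcortical voxel layer
beneath each CU seeds deterministic streamline tractography (FA threshold
0.14, turning-angle threshold 45°, step 0.5 mm, momentum smoothing 0.5,
1 seed/voxel, fibers kept at 30–300 mm), and

```
FiCD = ( Σ_fibers  mean-FA of fiber ) / seed volume [mm³]
```

is assigned back to the CU. Subject maps are surface-smoothed (10 mm FWHM),
Z-transformed against the hemisphere, and compared vertex-wise between two
groups with an OLS GLM; cluster-wise multiple-comparison control uses a
Monte Carlo simulation of smoothness-matched null z maps on the same mesh.
Post-hoc ROI analyses extract per-subject cluster means (FiCD, GM volume,
fiber number, mean fiber FA), compare groups (pooled t or Mann–Whitney U
after a normality gate), and compute partial correlations with a severity
score controlling for total brain volume.

The package is aimed at researchers prototyping surface-based structural
connectivity analyses and at anyone needing a tested, deterministic
reference implementation of this mapping pipeline on synthetic data.

## Worked example

```r
library(ficdmap)

# a 60 mm box with one straight high-FA bundle, and a spherical cortex
spec <- phantom_spec(
  grid_shape = c(30, 30, 30), voxel_size = 2,
  bundles = list(list(points = cbind(c(-10, 70), 29, 29),
                      radius = 8, fa = 0.8)),
  fa_background = 0.05, mesh_subdiv = 3, mesh_radius = 20)
vol  <- make_tensor_phantom(spec)
mesh <- make_cortex_mesh(spec)

parc <- parcellate_surface(mesh, K = 60, rng_seed = 2)
parc
#> parcellation: 60 cortical units, area 62.7-93.7 mm^2 (median 87.3)

fm <- ficd_map(vol, parc, tracking_params())
fm
#> ficd_map: 642 vertices, 60/60 CUs defined, FiCD 0-0.1
```

The per-CU FiCD is zero where only sub-threshold background FA lies beneath
the surface and rises to ≈ 0.1 for the units whose seed layer meets the
bundle (each seed voxel there contributes one ~58 mm fiber of mean FA 0.8,
divided by the unit's seed volume). A two-group cohort with a focal
decrease is then analyzed with:

```r
cohort <- make_cohort(mesh, cohort_spec(
  effect_vertices = geodesic_patch(mesh, 1, 60),
  effect_size = -0.3, rng_seed = 1))
maps <- smooth_surface_map(mesh, cohort$ficd, 10)
maps <- apply(maps, 2, z_transform_hemisphere)
stat <- glm_group_contrast(cohort, maps = maps)
cl <- monte_carlo_cluster_correct(mesh, stat,
        fwhm = estimate_map_fwhm(mesh, stat$residuals),
        n_iter = 1000, rng_seed = 3)
cl
#> cluster_results: 4 cluster(s) at cf_p = 0.05 (null: 1000 iterations, FWHM 15.6 mm)
#>   1: decrease, 64 vertices, 500.9 mm^2, corrected p = 0.02498 *
#>   2: increase, 52 vertices, 401.9 mm^2, corrected p = 0.07393
#>   3: increase, 14 vertices, 107.4 mm^2, corrected p = 0.6224
#>   4: increase, 8 vertices, 68.1 mm^2, corrected p = 0.7263
```

The significant decrease cluster is the injected patch (plus the smoothing
halo); its corrected p is the plus-one Monte Carlo estimate. `roi_report()`
then produces the per-cluster group tests and partial correlations, and
`run_pipeline()` chains all stages with one seed and writes a provenance
record with per-artifact MD5 digests.

A command-line front end mirroring these functions (subcommands `run`,
`simulate`, `parcellate`, `track`, `ficd`, `smooth`, `glm`, `mcz`, `roi`)
is installed at `inst/cli/ficdmap`.

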