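---
title: "Fiber connectivity density mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber connectivity density mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ficdmap)
```

## The measurement

Fiber connectivity density (FiCD) quantifies how much white-matter
connectivity converges on a unit patch of cortex. The gray--white matter
(GM--WM) interface is partitioned into K approximately equal-area *cortical
units* (CUs; 2000 per analyzed surface by default). For each CU, the
subcortical voxel layer directly beneath it seeds deterministic streamline
tractography on the diffusion-tensor field, and

$$\mathrm{FiCD} = \frac{\sum_{f \in \text{fibers}} \overline{\mathrm{FA}}_f}{V_{\text{seed}}},$$

the per-fiber mean fractional anisotropy summed over the CU's retained
fibers, divided by the CU's seed volume in mm^3 (the division corrects for
residual inhomogeneity in CU size). The value is assigned back to the CU's
vertices, smoothed along the surface with a 10 mm FWHM kernel, Z-transformed
against the whole-hemisphere mean and SD, and compared vertex-wise between
groups with an ordinary-least-squares GLM. Cluster-wise multiple-comparison
control uses a Monte Carlo simulation of smoothness-matched null z maps on
the same mesh. Post-hoc ROI analyses extract per-subject cluster means,
compare them between groups (pooled t, or Mann--Whitney U when a
Shapiro--Wilk check rejects normality at p < 0.05), and compute partial
correlations with a severity score controlling for total brain volume.

Everything is exercised on synthetic phantoms with known ground truth:
hard-tube tensor fields, icosphere or folded closed meshes, and two-group
cohorts with a configurable focal effect.

## Tracking model and parameters

The tracker integrates the principal eigenvector field bidirectionally from
each seed-voxel center with the classic deterministic parameter set:

| parameter | default | meaning |
|---|---|---|
| `fa_threshold` | 0.14 | terminate when interpolated FA drops below |
| `turning_angle_deg` | 45 | terminate when the field turns more than this |
| `step_mm` | 0.5 | integration step (mm) |
| `smoothing` | 0.5 | momentum weight s: new direction is normalize((1-s) v_field + s v_prev) |
| `seeds_per_voxel` | 1 | seeds per mask voxel, at the voxel center |
| `min_len_mm`, `max_len_mm` | 30, 300 | retained fiber length range (closed interval) |

Choices that the parameter names alone do not pin down, fixed here once:

* **Step units.** The step size is interpreted in mm (the length filter is in
  mm, so a voxel-unit step would make the two inconsistent under anisotropic
  voxels).
* **Turning-angle operand.** The 45 degree rule is applied to the angle
  between the *raw field direction* and the previous step direction. Applied
  after the momentum blend it could never fire: with s = 0.5 a 90 degree
  field flip blends to a 45 degree step, and a tracker that follows it walks
  smoothly through an orthogonal interface. Because the blend lies between
  the previous direction and an accepted field direction, consecutive step
  directions automatically satisfy the same bound, which keeps emitted
  polylines re-checkable.
* **Bidirectionality.** Each seed is tracked along +v and -v and the
  branches concatenated; surface-layer seeding otherwise loses half of every
  fiber.
* **Mean fiber FA** is the unweighted mean of FA sampled at the polyline's
  points; the alternative reading (summing FA at every tracked point rather
  than per-fiber means) changes the FiCD scale but not its structure, and is
  not the default.
* Tensor interpolation is component-wise trilinear followed by
  eigen-decomposition, with the eigenvector sign aligned to the previous
  direction (tensors are sign-symmetric).

## Parcellation

The parcellation seeds K vertices by farthest-point sampling over the
edge-weighted vertex graph, then grows all K regions simultaneously over the
face-adjacency graph with *area balancing*: the region with the smallest
accumulated area always claims its frontier face nearest its seed. This is
deterministic given the sampling seed, produces edge-connected, face-disjoint,
non-empty patches by construction, and keeps the max/min patch area ratio
below 3 on a sphere at K = 2000. A plain geodesic-Voronoi assignment was
tried first and rejected: at ~10 faces per patch its area ratio exceeded 20,
which defeats the purpose of equal-area units. Patch areas sum exactly to
the mesh area because faces are never split.

The seed layer beneath a patch contains every voxel whose center lies within
one voxel (`thickness = mean(voxel_size)`, configurable) of the surface on
the inward-normal side; a voxel claimed by several patches goes to the patch
holding its nearest surface point, so masks are always disjoint. CUs whose
seed layer comes out empty are flagged and excluded from statistics rather
than given an arbitrary value. K counts units per analyzed surface mesh
(i.e. per hemisphere when hemispheres are processed separately).

## Surface smoothing and its calibration

Smoothing is iterated area-weighted neighbor averaging,
`x <- x + lambda * A^{-1} L x`, with `A` the diagonal vertex-area matrix and
`L` a symmetric graph Laplacian. Because `L` has zero column sums the
area-weighted mean is conserved exactly, and constants are fixed points. The
iteration count for a requested FWHM is calibrated on the mesh itself: white
noise is smoothed until its realized FWHM (below) reaches the target. The
step size `lambda` is kept small (a quarter of the stability bound) so the
calibration can hit the target FWHM with fine granularity. An independent
check smooths a point mass and recovers the kernel width from its second
moment; on the subdivision-4 sphere the two agree to about 2%.

Realized smoothness is estimated from the neighbor-difference ratio: for a
field smoothed by a Gaussian of width sigma the correlation at distance d is
exp(-d^2 / (4 sigma^2)), so `rho = 1 - mean(edge diff^2) / (2 var)` at the
mean edge length identifies sigma, and FWHM = sqrt(8 log 2) sigma. For
spatially uncorrelated maps rho is ~0 and the estimate is reported as 0.

## Monte Carlo cluster-wise correction

Observed clusters are edge-connected components of vertices with GLM
p below the cluster-forming threshold (0.05 two-sided), split by effect sign
and sized by summed per-vertex area in mm^2 (not vertex count, for mesh
resolution independence). The null is built per iteration by synthesizing
Gaussian noise on the mesh, smoothing it to the FWHM estimated from the GLM
residuals, re-standardizing, thresholding at the two-sided z quantile, and
recording the maximum cluster area across both signs. Corrected p uses the
plus-one estimator (1 + exceedances) / (1 + iterations), which never returns
zero.

Two details of the re-standardization matter and were settled by simulation:

* **Scale.** Each null map is scaled by the *process-level* per-vertex SD of
  the smoothed-noise ensemble (estimated once from a 256-map calibration
  sample), not by its own spatial SD. Self-scaling shrinks exactly the maps
  that carry large excursions, truncates the null's upper tail, and inflated
  the empirical family-wise error rate to ~0.16 in a 38-subject t-map
  simulation; process-level scaling brings it back near the nominal 0.05.
* **Centering.** Analysis maps are hemisphere-centered by the Z-transform,
  so their group-contrast maps carry no global mode. Null maps are therefore
  centered per map; leaving the random global mode in makes null clusters
  systematically larger and the correction conservative.

Even so, the method is mildly conservative at desk scale: per-subject
Z-transformation removes a couple of spatial degrees of freedom from each
subject's field, which is noticeable when the mesh only holds a few dozen
smoothness resels. The package's null-calibration study (200 null cohorts of
20 + 18 subjects on a subdivision-4, radius-50 mm sphere, 500 null
iterations each) measures a family-wise error rate of about 0.02-0.04 at
alpha = 0.05.

## The synthetic cohorts

`make_cohort()` draws, per subject, a vertex map
`base + effect + noise` on a shared mesh:

* the base pattern is a fixed smooth function of position (so hemisphere SD
  is dominated by stable anatomy, as in real FiCD maps);
* the effect adds a per-subject realized magnitude (group mean
  `effect_size` in group A, 0 in group B, between-subject SD `effect_sd`)
  on a chosen vertex patch;
* the noise field is independent across subjects and *spatially smooth
  within* a subject (white noise smoothed to `noise_fwhm`, default 12 mm,
  rescaled to `between_subject_sd`, default 0.1). Spatially white noise was
  rejected: the analysis smoothing collapses it by a factor of ~4, after
  which the global mean shift that hemisphere Z-transformation induces for
  any focal effect (effect times patch fraction) dwarfs the residual noise
  and floods the GLM with artifactual "significant" cortex. Coherent
  between-subject variability is also what real surface maps show.

Severity scores follow `30 + a * realized_effect + noise`, so
partial-correlation analyses have a known sign and strength; gray-matter
volume maps are vertex area times a 2.5 mm nominal thickness with 10%
multiplicative noise; total brain volume is drawn near 1.4 L.

Shared mesh topology across subjects *is* the package's inter-subject
correspondence: it stands in for spherical surface registration, which is
out of scope. Consequently the phantoms cannot probe registration error,
MRI noise (Rician), distortion, or partial-volume effects: bundle tubes are
hard-edged precisely so analytic expectations stay exact. Passing tests
show the pipeline's statistics and geometry are right, not that acquisition
artifacts are handled.

## Study conditions used by the tests

The test suite and the acceptance script run fixed, documented problem
sizes: parcellation at K = 2000 on a subdivision-5 icosphere (10242
vertices, 20480 faces, radius 50 mm); the null-calibration study on the
subdivision-4 sphere (2562 vertices, 200 cohort replicates, 500 null
iterations); effect recovery (-3 x between-subject SD on a 200-vertex
geodesic patch, ~2% of the mesh) on the subdivision-5 sphere. The effect
patch is kept a small fraction of the surface deliberately: hemisphere
standardization couples any focal effect to the global scale, and with a
patch at ~8% of the surface that coupling alone produces spurious
significant cortex — on real whole-cortex meshes (~150k vertices) clusters
of a few hundred vertices are well under 1%.

## Pipeline order and degenerate inputs

The subject pipeline runs smoothing first, then the Z-transform, then the
GLM (both orders are defensible; this one standardizes exactly the maps the
GLM sees, and is configurable via the stage toggles). Other conventions:
voxel indices are 0-based with world positions at voxel centers; Z-transform
uses the sample SD; `fwhm = 0` is the identity; a zero seed volume makes
FiCD undefined (NA) rather than infinite; zero pooled variance yields t = 0,
p = 1 for equal means; `thickness = 0` gives an empty seed layer; rank
deficiency in the GLM design is an error naming the collinear columns, not a
silent drop. All generators and Monte Carlo routines take explicit seeds,
restore the caller's RNG state, and are bit-reproducible; the pipeline
derives per-stage child seeds from one master seed by a stable hash.

## Known limitations

* The Null-Z correction synthesizes Gaussian fields; at 36 degrees of
  freedom the observed maps are t fields, and the residual mismatch (plus
  the Z-transform's degree-of-freedom removal) leaves the correction
  slightly conservative at small mesh sizes.
* FWHM estimation assumes an approximately stationary field and a
  near-uniform mesh; strongly graded meshes would need a per-edge-length
  weighting.
* Endpoint-based fiber-to-CU assignment (a fiber crediting the CUs it
  terminates in, rather than the CU that seeded it) is not implemented; the
  seeding-CU convention follows the mapping framework's own definition.
* The phantoms' severity and GM-volume models are deliberately simple
  linear couplings; they test recovery of sign and approximate magnitude,
  not realistic psychometric structure.
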