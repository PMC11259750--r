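---
title: "Quantifying rotator cuff muscle architecture from diffusion tensor fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rotator cuff muscle architecture from diffusion tensor fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffarch)
```

## The measurement problem

The force-generating capacity of a skeletal muscle is governed by its
architecture — volume, fascicle length, pennation angle, and physiological
cross-sectional area (PCSA = volume / mean fascicle length) — together with
its moment arm about the joint it crosses. For the four rotator cuff muscles
(supraspinatus, subscapularis, infraspinatus, teres minor) these quantities
can be measured in vivo by combining anatomical MRI segmentations with
diffusion tensor imaging (DTI): water diffuses preferentially along muscle
fibres, so the principal eigenvector of the local diffusion tensor tracks
the fibre direction, and deterministic streamline tractography reconstructs
fascicles in 3D.

`cuffarch` implements the downstream analysis of such data: surface meshing
and volumetry of tissue label maps, deterministic fibre tractography with
anatomical endpoint constraints, per-fascicle architecture metrics,
geometric glenohumeral moment arms, and the variability / reliability
statistics used to summarise a cohort. Because in vivo scan data of this
kind are not generally redistributable, the package also ships a
first-class synthetic phantom generator whose closed-form ground truth
exercises every stage end to end.

## The processing model, stage by stage

### Label maps to meshes

Segmentations enter as integer label maps (0 background, 1 muscle,
2 aponeurosis, 3 bone) with a voxel-to-world affine (NIfTI convention,
world units mm). `surface_from_labels()` triangulates the 0.5-isosurface of
a binary label mask. The isosurface is extracted with a
marching-tetrahedra scheme: each grid cell is split into six tetrahedra
around its main diagonal and each tetrahedron is triangulated by linear
interpolation along its edges. This is a variant of marching cubes with no
ambiguous configurations, and the shared-diagonal decomposition guarantees
a watertight surface. Muscle volumes come from `enclosed_volume()`, the
divergence-theorem signed-tetrahedron sum, reported in cm^3 and insensitive
to face orientation.

Two numerical properties matter in practice:

* **Volume** of the raw (unsmoothed) isosurface converges quickly to the
  analytic value — about 3% error for a 10 mm sphere at 2 mm voxels, 0.5%
  at 1 mm, 0.05% at 0.5 mm. Volumes are therefore measured on unsmoothed
  meshes, and `smoothing_iters` defaults to 0.
* **Area** of a binary-mask isosurface is inflated by staircase facets
  (~28% for that same sphere). When surface area itself is of interest a
  few Laplacian smoothing passes (`smooth_mesh()`, 3–5 iterations) remove
  the staircase at a sub-percent cost in volume.

Proximity queries (`faces_within()`, `point_mesh_distance()`) use exact
point-to-triangle distances, not face-centroid distances, so results do not
depend on how finely a surface happens to be triangulated.

### Deterministic constrained tractography

`propagate()` integrates a streamline bidirectionally from a seed with
fixed-step Euler steps along the trilinearly interpolated tensor's
principal eigenvector, with eigenvector sign chosen for continuity with the
direction of travel. The default `track_params()` follow standard muscle
DTI practice: step 1.0 mm, fractional anisotropy gate [0.1, 0.5], maximum
turning angle 15 degrees between successive steps, accepted tract length
25–200 mm, and 3000 tracts per muscle. Each half of a streamline stops
when FA leaves the gate, the turn limit is exceeded, the tensor is
degenerate (leading eigenvalue gap below 1e-9 relative), or the path leaves
the muscle mask or grid. On a mask/grid/FA exit the final point is refined
by bisection onto the constraint boundary, so endpoints land on the tissue
interface rather than up to a full step short of it — without this, mean
fascicle lengths would be biased short by roughly one step.

The anatomical constraint (`act_accept()`) is an endpoint classification:
a tract is kept only if one endpoint lies within a tolerance (default half
the voxel diagonal) of the aponeurosis mesh and the other within tolerance
of the muscle's fascicle-exit surface, with its arc length inside the
accepted bounds. Endpoints near the aponeurosis are classified as
aponeurosis terminations even when the aponeurosis abuts the muscle
boundary surface. Rejections are tallied by cause (`too_short`,
`too_long`, `both_ends_same_structure`, `unterminated`), and
`sample_tracts()` draws uniformly random in-mask seeds (jittered voxel
centres) until the requested number of tracts is accepted or a budget of
100 attempts per requested tract is exhausted.

The integrator was validated against analytic fields: in a uniform field
the streamline is exactly straight and spans the mask; in a tangential
(circular) field at 0.2 mm steps the reconstructed arc matches the
analytic arc length within 1% and the circumradius of point triples
recovers the fibre circle radius; and tracking is equivariant under rigid
transforms of field, seed, and meshes to better than 1e-6 mm.

### Architecture metrics

Fascicle length is the polyline arc length. The pennation angle of a
fascicle is measured at its aponeurosis-terminating end: the fascicle
direction is the unit chord over the last 3 mm of arc (a single terminal
segment is noise-sensitive; 3 mm corresponds to three integration steps),
and for every aponeurosis face within 1.5 mm of the endpoint the angle
between that direction and the face plane is computed and folded into
[0, 90] degrees; the per-fascicle angle is the mean over those faces.
Fascicles with no face within the search radius yield a missing pennation,
are excluded pairwise from summaries, and are counted in the summary
record. `summarize_muscle()` reports means, medians, and sample SDs
(n − 1 throughout), intramuscular coefficients of variation
(100 × SD / mean), and PCSA; the identity
PCSA × (mean length / 10) = volume holds to machine precision by
construction.

### Moment arms

The glenohumeral centre of rotation is estimated by fitting a sphere to
points on the humeral-head articular surface: an algebraic linear
least-squares fit provides the initial centre and radius, and Gauss–Newton
refinement then minimises the sum of squared geometric residuals. The
muscle's line of action is a per-axis cubic polynomial through at least
four ordered tendon landmarks (insertion first), parameterized by
normalized chord length — uniform parameterization would distort curvature
for unevenly spaced landmarks. Four landmarks are interpolated exactly;
more are fitted by least squares. The moment arm is the minimum distance
from the curve to the centre over the landmark span t in [0, 1], found by
dense sampling (1000 points) plus local refinement; the search is not
extrapolated beyond the landmarks, and a minimum pinned at either end of
the span is flagged as a boundary minimum so the caller can extend the
landmark cluster.

### Variability and reliability statistics

Three nested levels of variation are reported as coefficients of
variation: intramuscular (across the 3000 fascicles of one muscle),
intermuscular (across muscle means), and interindividual (across subject
means). Test–retest reliability of paired measurement sessions uses the
two-way random-effects, absolute-agreement, single-measure intraclass
correlation ICC(2,1),

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with mean squares computed from closed-form two-way ANOVA sums of squares
and the standard F-based 95% confidence interval for the
absolute-agreement form. The implementation was cross-checked against an
independent ICC implementation (point estimate and interval agree to
1e-6) and against `stats::aov()` mean squares in the test suite. Note the
point estimator's known negative small-sample bias: at n = 10 and true
ICC 0.5 the mean estimate is about 0.43. This is a property of the
standard estimator, not of this implementation; recovery at n = 1000 is
within 0.01 and interval coverage at n = 10 is ~0.95.

The mean absolute difference between paired sessions is reported as a
percentage of the pair mean by default (symmetric in session order); the
first measurement can be chosen as denominator via a flag. Sex
comparisons use the unpaired two-sample t-test, Welch by default with a
pooled-variance flag, since the equal-variance assumption is rarely
justified for volume data; degenerate zero-variance inputs with equal
means return p = 1 by convention. No multiple-testing correction is
applied — raw p-values are reported per comparison. Cohort reports keep
the mean-of-ratios PCSA (per-subject PCSAs averaged) distinct from the
ratio-of-means cross-check (mean volume over mean length), which
deliberately may differ.

## The phantom: what it emulates and what it does not

`build_unipennate()` / `build_bipennate()` generate a pennate muscle with
a planar internal aponeurosis and straight fibres at a nominal angle
$\alpha$ to it, spanning a slab of thickness $t$, so the true fascicle
length is $t / \sin\alpha$ in closed form. The muscle occupies a sheared
prism whose side faces are parallel to the fibre direction, so every fibre
runs the full aponeurosis-to-exit distance and the fascicle-exit surface
(the slab face opposite the aponeurosis) is returned as a separate open
mesh for endpoint classification. In-muscle voxels carry a constant tensor
with the spec's eigenvalues (default (1.7, 1.2, 1.2)×10^-3 mm^2/s,
FA ≈ 0.21, inside the tracking gate); the bipennate variant mirrors the
fibre population across a central aponeurosis.

Intramuscular heterogeneity is injected as a smooth sinusoidal modulation
of slab thickness along the fibre-transverse axis (one full period across
the phantom, random phase per seed), with amplitude set so the SD of fibre
lengths across the phantom equals `length_jitter_sd`. A smooth modulation,
rather than per-voxel noise, keeps the tensor field spatially coherent, as
tracking assumes. Two consequences are worth knowing. First, uniform
in-mask seeding is volume-weighted: thicker regions attract more seeds, so
the tract-sampled length CV under a 30% injected CV is expected at ~26%
(the closed-form prediction for length-biased sampling of the sinusoidal
profile), which is what recovery experiments return. Second, the true
spatial statistics of intramuscular heterogeneity in real muscle are
unknown; the jitter magnitude is a free parameter of the phantom, not an
estimate of biology.

The phantom emulates the geometric and statistical structure the analysis
assumes — coherent fibre fields inside the FA gate, meshes bounding the
fibre region, landmark clusters on a curve of known distance to a known
centre, and two-session cohorts with stated variance components. It does
not simulate MRI physics: no noise model, eddy currents, susceptibility
distortion, or partial-volume fat/water effects. Passing phantom recovery
therefore demonstrates the correctness of the geometry and statistics
pipeline, not robustness to acquisition artefacts.

Companion generators cover the remaining stages: `build_articular_surface()`
(noisy spherical cap), `build_tendon_landmarks()` (landmarks exactly on a
cubic curve tangent to the sphere of the requested moment arm),
`build_reliability_cohort()` (two-way random-effects tables with known
ICC), and `build_cohort()` (per-subject architecture tables with a
Dirichlet draw around the canonical 43/34/15/8% relative-volume split and
a configurable male/female volume ratio; the default cohort is 11 males
and 9 females).

## Worked example

```{r example, eval = FALSE}
ph <- build_unipennate(phantom_spec(pennation_deg = 30,
                                    slab_thickness_mm = 25, voxel_mm = 1))
ts <- sample_tracts(ph$tensors, ph$label_map$voxels == 1,
                    ph$aponeurosis, ph$fibre_exit,
                    track_params(), seed = 42)
rec <- fascicle_records(ts, ph$aponeurosis)
summarize_muscle(rec, ph$measured_volume_cm3, muscle_name = "phantom")
#> phantom: volume 42.7 cm^3
#>   fascicle length 50.0 (median 50.0, SD 0.0, CV 0%) mm
#>   pennation 30 (SD 0, CV 0%) deg [0 missing]
#>   PCSA 8.5 cm^2 over 3000 tracts
```

## Numerical choices and degenerate inputs

* Coordinates are world mm throughout; voxel indices are 0-based with the
  affine mapping indices to voxel centres.
* Tensor components are stored and written in lower-triangular order
  (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), recorded in the NIfTI description field.
* Boundary bisection uses 40 iterations (sub-nanometre in the step
  parameter); endpoint refinement makes tract endpoints land on the
  trilinear 0.5-level of the mask, the same surface marching tetrahedra
  approximates.
* Degenerate tensors (leading eigenvalue gap < 1e-9 relative) stop
  tracking; all-zero tensors are an error for `fa()`.
* Sphere fits reject coplanar point sets (third singular value below 1e-9
  of the first); line-of-action fits reject coincident consecutive
  landmarks.
* Problem sizes in the test-suite and acceptance runs: phantoms of
  ~90×40×48 mm at 1 mm voxels with 3000 accepted tracts; CV recovery over
  5 seeds at 600 tracts each; ICC interval coverage over 500 replicates of
  n = 10; type-I error over 1000 null cohorts. These sizes give Monte-Carlo
  errors comfortably below the assertion tolerances.

## Known limitations

* The tractography is a faithful but minimal deterministic integrator; it
  does not reproduce any particular scanner pipeline's interpolation or
  masking details, and no probabilistic variant is provided.
* The anatomical constraint is an endpoint-to-mesh classification, not a
  tissue-probability framework; it requires meshes that actually bound the
  fibre region.
* PCSA is computed at measured (not optimal) fascicle lengths and cannot
  be converted to maximum isometric force without sarcomere-length data.
* Moment arms are evaluated at a single posture; no tendon wrapping or
  joint-angle sweeps.
* Reported intramuscular CVs mix true architectural variation with
  tracking measurement error; the phantom quantifies the pipeline's
  contribution under ideal tensors only.
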