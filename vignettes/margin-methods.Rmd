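---
title: "Biomechanical and statistical internal margins for pose variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanical and statistical internal margins for pose variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the models, their assumptions, the tunable parameters, the design of the
synthetic phantom cohort, and the numerical choices. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## Problem

In fractionated head-and-neck radiotherapy the patient is re-positioned
daily; image guidance removes the rigid part of the setup error with a
couch correction, but posture differences — neck flexion, shoulder
elevation — remain as *deformations* of the anatomy around the clinical
target volume (CTV). The package derives an internal target volume (ITV)
from the CTV to absorb these residual deformations, and evaluates three
competing constructions under a leave-one-out cohort protocol.

## Landmark pipeline

Bony landmarks (24 per patient: skull, spine, shoulder) represent the
pose. Tracking across fraction images uses 3-D normalized
cross-correlation template matching (`ncc_track()`); NCC is an absolute
conformity score, so correspondences with a score below 0.7 are marked
invalid — this catches landmarks outside the field of view. Positions are
voxel-grid positions; no subvoxel refinement is applied, and the argmax
tie-break is the first offset in lexicographic voxel order, for
determinism.

Landmarks on the same bone cannot change their mutual distance, so the
distribution (mean, covariance) of each same-bone difference vector is
estimated over a training set (`fit_geometric_model()`); covariances are
ridge-regularized with `1e-6 mm² · I` because small training sets make
them singular. A landmark's plausibility score is the *minimum*
Mahalanobis distance over its valid same-bone neighbors — a blunder
violates all of its edges, while taking the minimum keeps landmarks that
agree with at least one neighbor. Head-region (skull/spine) landmarks are
invalidated strictly above 15, shoulder landmarks strictly above 60 by
default; both thresholds are exclusive ("higher than") and configurable,
including the direction of the shoulder rule, since shoulders plausibly
move far more than the head. Invalid landmarks are carried as validity
flags and never imputed; the pipeline tolerates substantial missingness
(the generator default is 16.6 %).

The daily couch correction is simulated by rigid Procrustes alignment on
the valid skull landmarks (`procrustes_align()`): rotation and
translation only — a treatment couch cannot scale a patient — with the
SVD sign correction excluding reflections, and at least three
non-collinear skull landmarks required. The transform is applied to all
landmarks; what remains (`residual_displacements()`) is the individual
deformation.

## Biomechanical model

The body is meshed with linear tetrahedra and treated as a homogeneous,
isotropic, linear-elastic continuum. Defaults: Young's modulus
`E = 10 MPa` (mid-range of reported soft-tissue values), Poisson's ratio
`0.45` — reported head-tissue values span roughly 0.29–0.49 and the
choice is exposed in the configuration; energies are insensitive to it at
the strains involved. Units are mm/N/MPa throughout, so forces are
Newtons.

Each landmark is attached to its containing tetrahedron by barycentric
coordinates and pulled toward its fraction position by a zero-rest-length
spring `f = k·d` evaluated at the *deformed* attachment point; spring
forces are lumped onto the element nodes by the barycentric weights.
Because the spring energy is exactly quadratic in the nodal
displacements, only the elastic side needs iteration. Large rotations at
small strains are handled co-rotationally: per element, the rotation is
extracted by polar decomposition (SVD) of the deformation gradient and
the stiffness warped as `R K Rᵀ`; a Newton-type loop with backtracking
line search iterates to a maximum nodal residual force below `1e-3 N`
(configurable, maximum 200 iterations; non-convergence returns the
partial result with a flagged report). No Dirichlet anchor is added: with
three or more non-collinear springs the spring stiffness itself pins the
rigid-body modes, and degenerate spring sets raise an error. Element
inversions are logged as warnings, not errors. Assembly and rotation
extraction run in compiled code; the sparse symmetric solve uses CHOLMOD
through the Matrix package.

The spring stiffness `k` is the single calibrated parameter
(`calibrate_spring_stiffness()`): a sweep over candidate values selects
the smallest `k` whose mean landmark-to-target residual is at most
0.5 mm. `k` and `E` act inversely — doubling both leaves the displacement
field unchanged — which is why only `k` is swept. With the default
material the phantom calibration lands at `k = 1000 N/mm` on a decade
grid; the residual-vs-k curve is monotone non-increasing (violations
would be logged).

The solved nodal displacements define a dense displacement field by
barycentric interpolation (`barycentric_map()`). Points outside the mesh
use the nearest tetrahedron by clamped-barycentric reconstruction with an
exterior flag. Masks are propagated by forward-warping foreground voxel
centers and nearest-voxel deposition, followed by a directional
crack-sealing pass: a background voxel with foreground on both sides
along some axis is filled. This seals the one-voxel planes that
deposition leaves under expansive warps while being an exact no-op on
un-warped masks (a plain morphological closing would round concave
staircases even under the identity, breaking voxel-exact identity
contracts).

## Cohort pose model

Per patient, aligned fraction landmark positions are stacked into pose
vectors (length 3M, landmark-major) and centered on the patient mean
(`build_pose_vectors()`); missing coordinates enter as zero displacement
(within-patient mean imputation) with the availability mask retained.
The cohort model is a maximum-likelihood probabilistic PCA
(`fit_ppca()`), computed in closed form from the eigendecomposition of
the sample covariance (the pose dimension, 72, is small — EM would add
nondeterminism for no benefit): 5 retained components, noise variance =
mean discarded eigenvalue, component variance = eigenvalue − noise
variance. When an availability mask is supplied the covariance is
estimated from pairwise jointly observed entries; mean imputation alone
attenuates every covariance entry by roughly the missingness rate, which
would make every sampled scenario cloud systematically too narrow.

Scenario sampling (`sample_pose_scenarios()`) draws the five coefficients
independently from zero-mean Gaussians with the component variances — the
natural generative choice; the distribution family is otherwise
unconstrained by the margin recipe — and maps them through the
components. No isotropic noise term is added by default: the retained
components alone describe *consistent* poses, and adding isotropic noise
would inflate margins by an unaccountable amount (a flag exists).

Scenarios for a target patient are anchored at that patient's mean pose.
With a large cohort the mean is first noise-reduced by a second PPCA over
the per-patient means (reconstruction = posterior mean, which shrinks
toward the inter-patient subspace). This estimator needs enough patients
to estimate that subspace: with fewer than `2·5 + 1 = 11` training
patients the reconstruction of a held-out patient's mean is dominated by
subspace error and the raw within-patient mean (standard error
`σ/√fractions`) is strictly better, so the pipeline then uses the raw
mean. On paper-sized cohorts (18 training patients) denoising is active.

## Margin engines

All engines operate on 1 mm³ binary voxel volumes; `1 ml = 1000 voxels`.

* **Constant** (`margin_constant()`): Euclidean-ball dilation via an
  exact distance transform, default radius 3 mm.
* **Distance-weighted** (`margin_distance_field()` /
  `margin_distance()`): per landmark and axis, the systematic component
  `Σ` (SD over patients of per-patient means) and random component `σ`
  (RMS over patients of per-patient SDs) are computed leave-one-out.
  At each CTV surface voxel the local per-axis margin is the
  inverse-distance weighted average (exponent 1, configurable) of the
  per-landmark margins — `1.96σ` per axis in CI mode (default) or
  `2.5Σ + 0.7σ` in the classical mode; both are provided because either
  reading is defensible. The margins are applied as per-axis ellipsoids
  stamped from every surface voxel; with a constant isotropic field this
  reproduces the constant engine voxel-for-voxel. Coincident
  landmark/surface points give the nearest landmark full weight. Where a
  scalar margin is needed the maximum axis value is used.
* **Biomechanical** (`margin_fem()`): every sampled scenario deforms the
  CTV through the FE solver's displacement field; a per-voxel
  accumulation count is thresholded at *strictly more than* 5 % of the
  scenarios (the "more than" is read as a strict inequality; threshold 0
  gives the union of all deformed CTVs). Raising the threshold can only
  remove voxels.

## Evaluation

Four metrics per patient/fraction (`internal_margin_volume()`,
`healthy_tissue_hit()`, `missed_ctv()`,
`distance_to_oar_slicewise()`), all voxel-counting on a shared grid with
center-to-center distances (at 1 mm the surface-vs-center ambiguity is
sub-voxel). The slice-wise organ-at-risk distance uses the *planning*
ITV against the cord propagated to each fraction — only the cord is
propagated. The leave-one-out protocol (`run_loocv_comparison()`)
guarantees that every statistic or model a patient's margin depends on is
built from the other patients; the ground-truth fraction CTVs come from
the generator's analytic deformations, never from the fitted model, so
model error shows up in the metrics instead of being hidden. Cohort
tables report percentage deltas against the constant-margin baseline.

## Synthetic phantom cohort

The phantom is a head sphere (r = 70 mm) on a neck cylinder (r = 45 mm)
on a shoulder slab (300 × 160 × 80 mm), with 24 landmarks (8 skull,
8 spine, 8 shoulder), a horseshoe CTV around the cord axis (a cylinder
with an 80° posterior wedge removed; the wedge is blunted within 8 mm of
the axis so the notch never narrows below voxel scale) and a posterior
spinal-cord cylinder (r = 5 mm). The CTV radius is solved from the
requested target volume (500 ml default, 120 ml in the `tiny` preset).
Meshing fills the implicit body with a structured grid split into six
conforming tetrahedra per cell (Kuhn subdivision) at a target edge length
of 15 mm (30 mm in `tiny`); imported meshes in legacy-VTK format are
supported as an alternative.

Fraction poses compose a random rigid setup transform (per-axis
translation SDs 0.73/1.08/1.76 mm, rotation SDs 1.06/0.70/0.92°, about
the skull centroid) with a smooth residual deformation built from four
analytic modes — lateral, dorsal-ventral, cranial-caudal, and a
left-right asymmetric cranial-caudal mode — weighted by a logistic
cranio-caudal ramp (near 1 at the shoulders, near 0 at the skull). The
cranial-caudal modes additionally carry a lateral arm-girdle weight:
the shoulder girdle rises almost rigidly while midline tissue follows
only partially. The amplitudes (2.5/2.5/8.5/8.5 mm) were set so that the
mean shoulder-landmark residual magnitude is ≈ 9.2 mm while the mean
deformation inside the CTV stays near 1–2 mm — the regime in which a
constant 3 mm margin is generous cranially yet tight caudally. Mode
coefficients are standard normal with a per-patient systematic component
(fraction 0.5 of the SD), giving each patient a reproducible habitual
posture. Observed landmark sets add isotropic tracking noise (0.5 mm SD)
and missingness (16.6 %); at least three skull landmarks are always kept
so the couch correction remains solvable. Ground truth (coefficients,
noise-free positions, analytic deformation fields) is retained alongside,
and the deformation fields are deliberately analytic — independent of the
FE solver — so solver accuracy is measured against an external truth
rather than against itself. An optional gross-blunder channel (25 mm,
default rate 0) exists to exercise the outlier filter.

What the generator does **not** emulate: realistic CT appearance,
swallowing/breathing motion, weight loss, heterogeneous tissue stiffness
(bone vs soft tissue), or joint articulation. Passing tests on this
cohort therefore demonstrate correctness of the pipeline mechanics and
the *direction* of the cohort-level comparisons, not clinical margin
magnitudes.

## Problem sizes and numerical choices

Tests and the acceptance script run the `tiny` preset: 120 ml CTV,
~30 mm mesh edge (≈ 1 600 tetrahedra), cohorts of 4–6 patients with 6–10
fractions, and 100 sampled scenarios for the biomechanical engine
(scaled down from the 400 used at full scale); these sizes were chosen so
a full cohort comparison completes in minutes on a single core while
leaving every contract measurable. Other fixed numerical choices:
covariance ridge `1e-6 mm²`; FEM tolerance `1e-3 N`, ≤ 200 Newton
iterations, backtracking line search halving up to six times; NCC
tie-break lexicographic; EDT exact (Felzenszwalb) with a large-finite
sentinel; voxel centers at half-integer offsets; strict inequalities at
the 0.7 NCC, Mahalanobis, and 5 % accumulation thresholds.

## Known limitations

* The variable-margin weighting (inverse distance, exponent 1) treats
  the patient as transparent: a landmark influences surface points even
  when the connecting line crosses air; the biomechanical engine is the
  remedy.
* The 5 %-of-scenarios rule trims the per-voxel coverage distribution at
  both tails, so the biomechanical ITV deliberately does not cover
  extreme poses; coverage-vs-volume trade-offs should be tuned with the
  `hit_threshold`.
* Homogeneous elasticity ignores bone; landmark springs partially
  compensate because the landmarks sit on bone.
* The mean-pose denoising needs cohort sizes of roughly a dozen patients
  to pay off (see above); the pipeline falls back to raw means below
  that.
* Forward mask warping with crack sealing is exact for identity and
  integer translations and bounded by the field's Jacobian otherwise,
  but it is a rasterization, not a surface transform: sub-voxel boundary
  effects of order one voxel are inherent at 1 mm resolution.
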