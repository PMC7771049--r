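---
title: "Methods: fusing, validating and measuring superficial cortical veins"
author: "veinfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusing, validating and measuring superficial cortical veins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(veinfuse)
```

## The problem

Neuronavigation is referenced to the skull, but the brain moves under it:
once the dura is open, CSF drainage, resection and pressure changes shift
the cortex by up to centimetres. Superficial cortical veins shift *with*
the cortex, which makes a preoperative reconstruction of cortex plus veins
a robust intraoperative map. Building such a reconstruction requires (i)
fusing a structural volume with a venous angiography volume, (ii) knowing
how accurate the (interactive) co-registration is, (iii) validating the
reconstructed veins against the real surgical site, and (iv) being able to
read anatomy — bridging-vein counts, confluence angles, drainage types —
off the reconstruction. `veinfuse` implements all four stages plus the
synthetic phantoms that stand in for patient data.

All geometry uses one convention: world coordinates are RAS millimetres
(+x right, +y anterior, +z superior), voxel indices are 0-based, and a
voxel's world point is its centre (`origin + index * spacing`).

## Fusion and thresholding

`fuseVolumes(primary, secondary, threshold)` copies the structural channel
and labels every voxel whose angiographic value is *strictly greater* than
the threshold. Strict inequality is used for every threshold in the
package, so "at the threshold" is never included. The monochrome colour of
the workstation overlay is presentation only; the data model stores a
boolean label.

The threshold has no published per-patient value; it is an input.
`thresholdSweep()` characterizes the trade-off: the labelled voxel count
is non-increasing in the threshold, and the number of connected components
of the label quantifies how "discontinuous and broken" the vessels become
when the threshold is too high. Connectivity is fixed at the
26-neighbourhood, the standard choice for thin 3D vessels; with 6- or
18-connectivity diagonal vessel steps would break and component counts
would not be reproducible across implementations.

## Rigid poses and the geometric centre

Interactive registration is represented by six parameters: translations
`(tx, ty, tz)` in mm and rotations `(rx, ry, rz)` in degrees.
`paramsToTransform()` fixes the convention `Translate(t) · Rz · Ry · Rx`,
right-handed, about the world axes at the origin. The workstation's own
rotation sequence is undocumented; any fixed, documented convention
preserves the error statistics, and reproducibility was preferred over
fidelity to an unknowable commercial convention.

The gold standard over repeated registrations is the *geometric centre*:
the component-wise mean of the six parameters (`geometricCenter()`).
Averaging is done in parameter space rather than on rotation matrices; for
the sub-degree angular spreads that matter here (spatial errors of about a
millimetre) the difference from proper rotation-group averaging is far
below the quantities being estimated. Quaternion or chordal averaging
would be the alternative if large rotational spreads ever became relevant.

## The Monte-Carlo spatial error

`mcSpatialError(trial, gold, mask, nPoints, seed)` samples `nPoints` voxel
centres uniformly *with replacement* from a cortex mask and returns the
mean Euclidean distance between the images of each point under the two
poses. Sampling voxel centres without intra-voxel jitter is the simplest
faithful reading of sampling "random pixels"; jitter would perturb each
distance by far less than a voxel and vanish in the mean. Distances are
always in world mm, never voxels. The estimate is deterministic given the
seed, symmetric in trial and gold, and exact (mask-independent, n-independent)
for pure-translation differences, where every point moves by `||t||`.

`exhaustiveSpatialError()` is the brute-force counterpart over every mask
voxel; the test suite uses it as the oracle the Monte-Carlo estimate must
track within its sampling error. `mcConvergence()` reports the standard
deviation of repeated estimates — the "variation" that justifies 5,000
points: on a 128³ cortex-shell mask with a ~0.9 mm perturbation the
spread of twenty 5,000-point estimates is well below 0.01 mm.

Per-unit aggregation (`trialSetErrors()`, `observerVariability()`) mirrors
the repeated-registration protocol: each trial is compared against the
trial set's own geometric centre. Those per-trial distances are therefore
not independent of the gold standard — the protocol defines them this way,
and the package computes exactly what is described. Unit means are
averaged unweighted into the intra- or interobserver grand mean, displayed
at two decimals with full precision retained.

## Sculpting and slice segmentation

`sculptCut()` removes every voxel whose orthographic projection along the
current view direction falls *strictly inside* a marked polygon — the cut
is depth-unbounded, matching removal "perpendicular to the viewing plane".
Voxel centres exactly on the polygon boundary are kept; the tie rule is
immaterial to any statistic but fixed for reproducibility. The background
sentinel is 0 for both modalities. Repeating a cut is idempotent, and a
sequence of cuts over rotated views equals removing the union of their 3D
regions, which is what makes the iterative "peeling" workflow
well-defined. `applySliceMasks()` implements the manual stamp-tool
segmentation: in `keep` mode only marked voxels survive on marked slices,
in `remove` mode marked voxels are cleared; unmarked slices are untouched.

## Views, projection and photo alignment

Six standardized views are defined in `standardView()`; all rendering is
orthographic, which keeps angles read from projections geometry-exact and
matches workstation renderings used for counting and angle reading. The
verbal view definitions ("30° frontal, 30° cranial") admit several
composition orders; the package fixes: views 2/3 tilt the cranial view 40°
toward frontal/occipital; views 5/6 start from the lateral view, apply the
sagittal-plane (frontal/occipital) tilt first, then the cranial tilt. The
in-plane "up" vector is the projection of +z (superior), falling back to
+y (anterior) for near-axial directions.

`mip()` renders a maximum-intensity projection on a regular pixel grid;
`projectPolylines()` maps vein centerlines through the same frame.

The photograph is modelled as an orthographic view composed with an
unknown 2D similarity (the manual rotate-and-scale alignment); perspective
and lens distortion are out of scope. `fitSimilarity()` solves the
orthogonal-Procrustes-with-scale problem in closed form (complex
least-squares, rotation only — no reflection) and recovers constructed
transforms to machine precision.

## Five-category validation

`classifySections()` reproduces the categorical bookkeeping exactly; only
the match score replaces expert eyes. The score is the mean symmetric
polyline distance: both traces resampled at 0.5 mm arc-length steps, the
two directed mean point-to-polyline distances averaged. It is zero on
coincident traces. Matching is greedy one-to-one in ascending score with a
deterministic tie-break (lower section index first), and only pairs within
`tol` match. Each matched pair is booked *once* as Category 0 — which is
what makes the three totals consistent (reconstruction-visible =
categories 0+2+3+4, photo-visible = 0+1, overall total = all five).
Unmatched photo veins are Category 1; unmatched reconstruction sections
are Category 3 if a photo artery trace lies within `tol`, Category 4 if at
least half their arc length falls inside an occlusion polygon, otherwise
Category 2. The artery check precedes the occlusion check.

The default `tol` of 3 mm is below typical inter-vein spacing (the
phantoms place bridging veins roughly 10-15 mm apart along the sinus) and
above tracing jitter; no published value exists, and it is configurable.

## Anatomy measurements

*Counts.* Bridging junctions are assigned to sinus thirds by arc-length
position with half-open intervals `[0, L/3)`, `[L/3, 2L/3)`, `[2L/3, L]`
(a junction exactly on a boundary goes posterior), and to a side by the
sign of the vein centroid's x-coordinate, with the exact midline going
left. Side totals are sums of the three thirds at full precision — the
published per-side totals differ from the sums of their rounded per-third
means by rounding only.

*Confluence angles.* The angle is measured between the vein's terminal
unit direction (from the junction away from the sinus, along the vein) and
the *posteriorly* oriented local sinus tangent, both projected into the
view plane of a cranial view, in `[0°, 180°]`. This convention makes
anterior frontal veins obtuse (~110°) and occipital veins acute (~10°),
the anterior-to-posterior pattern the readings must reproduce; the
original geometric derivation is not available, so the convention is fixed
here explicitly, and the true 3D angle is reported alongside for
comparison. The terminal direction is the chord over the first 5 mm of
the centerline (configurable), damping tracing noise. The measurement is
invariant to uniform scaling and to in-plane rotation of the scene.

*Group statistics.* `groupAngleStats()` computes per-group mean and MAD
(`mean(|x - mean(x)|)`), selecting at most two veins per group per unit,
largest calibers first, mirroring the two-veins-per-group sampling rule.

*Drainage types.* The published Type I-V definitions live in an external
reference not reproduced here; `classifyDrainage()` is an explicit,
parameterized stand-in on the caliber ranking of the Trolard, Labbé and
superficial Sylvian veins (balanced within ratio 1.5 → I; single dominant
→ II/III/IV; one absent below 0.3 mm with the other two co-dominant → V).
It must not be read as the published classification; it is deterministic,
configurable and exactly invertible by the phantom generator.

## The phantom generator

`generatePhantom()` encodes the emulated study conditions as defaults:

* six angle groups with means 103.5/85.2/69.5/61.1/47.0/39.3° and MADs
  14.5/10.3/15.3/11.9/11.2/7.9°;
* per-third per-side mean counts 4.3/4.4/2.3 (left) and 4.1/4.5/2.0
  (right), Poisson-distributed (or fixed on request);
* drainage-type frequencies 9:3:3:3:1 over a cohort of 19;
* a 128³ grid at 1.5 mm isotropic — large enough for ~0.9 mm error fields
  to be well resolved, small enough for full-pipeline runs at desk scale;
* vein radii 1-3 mm, tube intensity 200 over Gaussian noise (SD 5), so the
  default threshold (half the tube intensity) segments essentially every
  centerline voxel.

Angles are drawn from a normal with `sigma = MAD * sqrt(pi/2)` (the
MAD-to-sigma relation *of a normal*; the distribution family is not
published and truncation makes the realized MAD slightly smaller),
truncated to per-group anatomical ranges assembled from the per-vein
ranges of the named veins draining each territory: [55,155], [20,160],
[15,105], [10,95], [0,55], [0,45] degrees. For the posterior groups these
ranges are strongly asymmetric about the mean, so the *mean of the
truncated distribution* — available in closed form via `truncnormMean()`
— is the generator's true mean, and parameter-recovery checks compare
measured group means against it rather than against the nominal value
(for the anterior frontal group the two differ by under 0.1°).

Vein geometry realizes each drawn angle exactly: the terminal 8 mm of
every vein lies in the cranial-view plane at the drawn angle to the
projected posterior sinus tangent, then the vein descends laterally. Truth
records therefore round-trip: counts are recovered exactly and angles to
well under 1°. Tubes are rasterized with an effective radius of at least
the voxel half-diagonal so thin vessels stay connected in the volume.

The simulated photograph applies, per vein, the confounder mechanisms that
define the five categories (dropout → 2, extra traces → 1, artery
substitution → 3, occlusion polygons → 4), i.i.d. Gaussian vertex jitter
on all marks, and a known misalignment similarity to the whole photo
frame. Alignment landmarks model cortical landmarks visible in both
media — the true projected polyline endpoints with independent per-side
jitter — so the photograph remains alignable regardless of which veins the
confounders remove. Smooth brain-shift-like deformation is deliberately
excluded: the premise of the whole method is that veins move with the
cortex, so at mark level a similarity suffices.

What the phantoms do *not* emulate: MR physics (inflow, coil profiles,
bias fields), gyral/sulcal cortical geometry, vessel tortuosity and
branching hierarchies, perspective and lens distortion in the photograph,
and real tracing behaviour of human raters. Passing the closed-loop tests
therefore shows the bookkeeping, geometry and estimators are correct — not
that the matching tolerance or the MR sequence would perform identically
on clinical data.

## Numerical choices and problem sizes

Tolerances in tests follow the estimator's own sampling theory (e.g. the
Monte-Carlo estimate must sit within a few standard errors of the
exhaustive oracle). Degenerate inputs fail loudly: empty masks, empty
trial sets, degenerate polygons, vein segments projecting to a point,
landmark sets with fewer than two distinct points. All stochastic
functions take an explicit integer seed and are bit-reproducible given it.

Default problem sizes were chosen once as desk-scale study conditions: the
convergence check uses the full 128³ mask; oracle-equivalence checks use
masks of at most 10⁵ voxels where exhaustive evaluation is exact and
cheap; parameter recovery uses 200 tree-only phantoms (volume
rasterization is skipped where only the geometry is measured — the
`volumes = FALSE` generator mode); the closed validation loop pools a
dozen phantoms at the default confounder rates.

## Known limitations

* The Euler convention, tilt composition order, matching tolerance and
  drainage rule are documented conventions standing in for undocumented or
  external originals; statistics are insensitive to the first two, and the
  latter two are explicit parameters.
* Parameter-space pose averaging is inappropriate for large rotational
  spreads (not the regime here).
* The patient-derived anatomy numbers (group angle tables, per-third count
  means, drainage frequencies) are not reproducible from data — no raw
  data exists; they enter only as generator defaults and
  parameter-recovery targets.
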