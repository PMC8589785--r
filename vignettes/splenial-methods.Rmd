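---
title: "Measuring the splenial angle: models, phantoms and the evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the splenial angle: models, phantoms and the evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splenial)
```

This vignette is the package's own account of its science: the measurement
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement problem

Idiopathic normal pressure hydrocephalus (NPH) presents with
ventriculomegaly at normal CSF pressure. Two quantitative radiological
indices are established: Evans' index (EI), a gross width ratio that is
sensitive but unspecific, and the callosal angle (CA), which is more
specific but measured on a reformatted coronal plane whose positioning is
error-prone. The splenial angle (SA) is an alternative *axial* angular
index read off directionally-encoded color (DEC) fractional-anisotropy
maps: the posterior callosal commissural fibres (splenium and forceps
major) are compressed medially by the distended posterior-medial
ventricular walls, so the angle subtended by the forceps-major limbs about
a midline pivot narrows dramatically in NPH.

All geometry uses a canonical right–anterior–superior frame: `x` left–right
(red on the DEC map), `y` posterior–anterior (green), `z` caudocranial
(blue). Axial slices are constant-`z`, ordered caudocranially, matching
acquisitions prescribed parallel to the AC–PC line. Angles are kept at full
double precision and rounded only for presentation (one decimal).

## 2. Diffusion model

`fit_tensor()` fits the single-tensor model
\(S = S_0 \exp(-b\, g^\top D g)\) per voxel by **unweighted log-linear
least squares**. This is the simplest defensible estimator; the SA is a
purely geometric readout of the DEC map and does not benefit from
estimator refinements (WLS/NLLS), so we deliberately avoid them. Negative
eigenvalues arising from noise are clamped to zero by spectral projection.
Voxels whose mean b=0 signal is below 1% of the volume's robust (98th
percentile) maximum are flagged background. A gradient scheme is accepted
only if its b>0 rows span all six tensor components (at least six
non-collinear directions).

FA and the principal eigenvector come from a vectorised closed-form
symmetric 3×3 eigendecomposition (trigonometric method; the principal
eigenvector via the spectral projector \((A-\lambda_2 I)(A-\lambda_3 I)\)).
The sign ambiguity of `e1` is resolved by making the largest-magnitude
component non-negative — cosmetic, since DEC encoding uses absolute values:
`rgb = FA · (|e1_x|, |e1_y|, |e1_z|)`. The scanner convention for the red
axis is not standardised across vendors; the canonical RAS convention
(red = left–right) is adopted and volumes must be supplied in that frame
(`nifti_read()` rejects oblique or permuted affines rather than guessing).

## 3. Operationalising the SA

The clinical definition leaves two things to the rater, both fixed here and
exposed as configuration:

**Complete callosal body.** The SA slice is the first caudocranial axial
slice containing the complete red-encoded callosal body. We operationalise
"complete" as: within a midline strip of half-width `strip_mm = 4` mm, the
red-dominant callosal voxels form a connected component whose
anteroposterior extent reaches at least `extent_frac = 0.9` of the maximum
such extent over all slices. Below the body, the genu and splenium appear
as separate blobs with short strip extents, so the criterion first holds
exactly where the body band connects them — which is what the rater
perceives as "complete". When several consecutive slices qualify (thick
body, thin slices), the caudal-most is used, extending the stated two-slice
caudal rule.

**Pivot and arms.** `fit_forceps_rays()` grid-searches the pivot along the
midline in 1 mm steps and, for each candidate, takes the mask voxels
*posterior* to the pivot within a 5–30 mm annulus, split left/right; each
limb's ray is the principal axis of its voxels (straight total-least-squares
rays — the source does not state how a curved limb is resolved, and
straight rays match the rater's straight-arm goniometer). The pivot
minimising the summed orthogonal voxel-to-ray distance wins. The posterior
restriction encodes that the forceps major, not the forceps minor, carries
the measurement. The pivot must lie within `midline_tol_mm = 2` mm of the
midsagittal plane (the tolerance is not stated clinically; 2 mm ≈ one
DTI voxel).

One subtlety fixed during development: the pivot-candidate extent is taken
from voxels that actually *straddle* the midline (within one voxel), not
from the full 4 mm strip. With near-parallel limbs (SA ≈ 20°) the strip
contains long stretches of limb, and a pivot at the limb tips can minimise
the summed cost degenerately; restricting the candidate extent to genuinely
midline voxels removes that failure mode without touching any stated
constant.

`detect_midline()` maximises mirror-symmetry overlap of the foreground in
half-voxel steps within ±10 mm of the geometric centre, falling back to the
centre (with a warning) when the best overlap is below 0.5. The whole chain
is deterministic: two runs on the same input are bit-identical, and every
intermediate choice is recorded in a JSON-serialisable audit trail.

## 4. The digital phantom

`make_phantom()` voxelises a stylised head: an ellipsoidal skull
(70×85×60 mm semi-axes), two lateral ventricles, and a callosal complex
(genu, midline body band, splenium bridge, forceps minor, and forceps-major
limbs). Ground truth is exact by construction:

* **SA**: the limbs are straight bars from a midline pivot at directions
  ±`true_sa`/2 off the posterior axis.
* **CA**: the ventricle-body roofs are planes whose coronal section makes
  the angle `true_ca` at a midline apex; the roof apex also rises
  anteriorly (slope 0.7), so a mal-angulated coronal plane mixes the
  anteroposterior variation into the apparent roof slope — this is what
  makes acute/obtuse mal-angulation (first order in the tilt) dominate
  right–left mal-rotation (second order) in `ca_tilt_experiment()`,
  reproducing the clinically observed asymmetry.
* **EI**: the frontal-horn half-width is `7 + 10.5·v` mm inside a 70 mm
  skull semi-axis, giving EI = 0.25 at `v = 1` and 0.40 at `v = 2`.

The ventriculomegaly factor `v ≥ 1` widens the ventricles and steepens the
roofs via `true_ca = 2·atan(tan(ca_at_v1/2)/v^{1.5})`; the exponent 1.5 is
a package choice that maps `v = 2` into the observed NPH CA range (~55°)
while keeping EI and CA strictly monotone in `v`, which is the property the
tests assert.

**Fibre directions.** Commissural voxels (body, genu, bridge) have `e1`
exactly left–right. Limb voxels take the limb tangent *partially rotated
30° toward the commissural axis*. A pure tangent would make every limb with
opening < 90° green-dominant and thus invisible to the red-dominance rule —
the two requirements (tangent fibres; red-dominant commissural mask)
conflict for every realistic SA. The partial rotation mirrors the
red-to-yellow appearance of the forceps on real DEC maps, and is harmless
to validity because the SA is measured from the limb *geometry*, never from
`e1` within the limbs. Tissue diffusivities: callosum prolate
(1.7, 0.3, 0.3)×10⁻³ mm²/s (FA ≈ 0.80), CSF 3.0×10⁻³, brain 0.8×10⁻³;
optional DWI synthesis (20 directions, b = 0/1000 s/mm²) with additive
Gaussian noise.

What the phantom does **not** emulate: anatomical curvature of the
callosum, partial-volume averaging, susceptibility distortion, Rician noise
floors, and pathology beyond symmetric ventriculomegaly. A green automated
SA test therefore establishes correctness of the geometry pipeline, not
clinical robustness.

## 5. The synthetic cohort

`simulate_cohort()` draws per-subject (EI, CA, SA) from group-specific
Gaussians with the canonical moments shipped in
`inst/extdata/group_moments.csv` (four groups of 19, ages and 11 M / 8 F
per group as in the source design), truncated by rejection to EI ∈ (0, 1)
and angles ∈ (0°, 180°). The published study reports only means ± SDs and
no cross-index covariance, so the default correlation is 0 and is exposed
as configuration; the reported qualitative ranges (NPH SA mostly < 35°,
non-NPH mostly > 45°) emerge from the moments and are not enforced.
`simulate_followup()` adds per-arm Gaussian deltas from
`inst/extdata/followup_deltas.csv` (6 shunted, 5 not; angles widen after
shunting, EI decreases slightly).

A green simulation test establishes that the statistical machinery
reproduces the published screening numbers *given* Gaussian marginals with
the printed moments — not that real NPH cohorts are Gaussian.

## 6. Statistical choices

* **ICC**: the named reliability model is fixed to ICC(A,1) — two-way,
  absolute agreement, single measurement — in the McGraw–Wong definitions,
  with the standard F-based confidence interval (Satterthwaite degrees of
  freedom). Constant ratings are flagged rather than returned as a number.
* **Pairwise comparisons**: the source names only "pairwise comparison
  adjusted by Benjamini and Hochberg"; two-sided Student t tests per pair
  with BH step-up over all six pairs are adopted (Welch available via
  `var_equal = FALSE`).
* **ROC**: empirical (Mann–Whitney) AUC with midrank tie handling; DeLong
  variance via placement values; the operating point minimises
  \((1-\text{sens})^2 + (1-\text{spec})^2\) over observed cutoffs, ties
  broken toward higher specificity and then the more extreme cutoff. SA and
  CA use `direction = "lower"` (narrow favours NPH), EI `"higher"`.
* **Stepwise prediction**: the selection criterion is unstated in the
  source; bidirectional AIC from the full model is used, with the full
  selection trace retained so alternatives can be compared. The simulated
  cohorts separate almost completely on SA, so separation is detected,
  flagged, and the final model's coefficients are refit with a small ridge
  penalty (the AUC ladder is rank-based and unaffected).
* **Shunt changes**: "Student's t test" is taken literally (pooled
  variance), Welch via configuration. Significance is two-sided 0.05
  throughout.

## 7. Numerical notes and limitations

* Angles are computed with the `atan2` half-angle form, stable near 0° and
  180°; degenerate landmark configurations warn (0°) or error (coincident
  points).
* Width measurements on voxel masks are outer-voxel-centre spans, biasing
  EI by at most half a voxel per edge; the acceptance criterion (|ΔEI| <
  0.01) holds at 1 mm in-plane spacing.
* `label_components()` and the mask machinery are pure R over sparse voxel
  sets; volumes around 10⁶–10⁷ voxels are comfortable, whole-brain
  sub-millimetre volumes are not the target.
* The automated chain assumes the input is already in the canonical RAS
  frame with a trustworthy left–right axis; it does not reorient, resample,
  or correct for motion/eddy currents, and it has only been validated on
  phantom-grade ventriculomegaly, not on atrophy patterns, midline shifts,
  or post-surgical anatomy.
* Replicated screening targets use 1000 seeded replicates; the replicate
  means are stable to ~10⁻³ in AUC across master seeds, well inside the
  stochastic tolerances they are compared at.
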