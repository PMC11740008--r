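---
title: "Digital-twin adaptive proton SBRT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin adaptive proton SBRT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two-fraction prostate SBRT delivers 13 Gy per fraction, so a single poorly
aligned fraction is half the treatment. Proton robust optimization replaces
the geometric PTV margin with worst-case optimization over setup-shift and
range scenarios, but clinics typically feed it one conservative, constant
setup uncertainty (here 5 mm in every direction, 3 mm posteriorly). If a
patient's prostate barely moves relative to the bony anatomy, that
conservatism irradiates bladder neck, bladder and rectum unnecessarily; if it
moves a lot, even 5 mm may be the wrong shape of allowance.

`protontwin` implements a digital-twin alternative: learn each patient's
plausible CTV (clinical target volume) position from geometric image
features, robustly plan *several* candidate plans spanning that patient's
uncertainty, and on each treatment day score every candidate against the
anatomy of the day and deliver the best one. No online re-optimization is
needed, only evaluation and selection.

## Coordinate conventions

All coordinates are mm in a fixed patient frame: +x patient-left,
+y posterior, +z superior. Margins are stated per direction in the order
(left, right, anterior, posterior, superior, inferior). A margin set's
"posterior 3 mm" therefore bounds growth in +y. This convention is required
to give direction-resolved statements a single meaning; it is asserted
nowhere else in the stack, so substituting a different frame only requires
relabeling at import time.

## Geometric features and the regression target

For every image (planning CT or treatment CBCT) the package reduces the
contoured anatomy to reference points: the CTV center of mass, and two
vertices of the single axis-aligned bounding box around the union of the two
femoral-head contours. FemL is the box vertex that is patient-left, posterior
and inferior; FemR the vertex patient-right, posterior and superior. The
inferior/superior asymmetry between the sides is part of the reference-point
definition this package follows; it is asymmetric on purpose and documented
here because it surprises first readers — the two vertices are *not* mirror
images, and the z-component of the regression target therefore carries the
full craniocaudal extent of the femoral box.

Seven features are computed per image: the FemL-FemR distance, the CTV-FemL
and CTV-FemR distances, the angle at the CTV between the two femoral
directions, and the three signed axis components of CTV - FemR. All seven are
invariant under rigid translation of the whole structure set, which matches
couch-shift image guidance. The regression target is the *relative CTV
position*, CTV center of mass minus FemL, per axis.

## The margin model

Three independent Gaussian processes (one per axis) map features to the
relative CTV position. Kernel: anisotropic squared-exponential with one
length scale per feature, plus observation noise; features are standardized
on the training data; hyperparameters maximize the log marginal likelihood
(analytic gradients, L-BFGS-B, five deterministic restarts). The predictive
variance includes the fitted noise, so `mu +/- 2 sigma` is a prediction
interval for a *new* treatment-day position, not just for the latent mean —
that is what margin construction needs.

Margins for a planning image are built from the predicted displacement
`d = mu - planning relative position` per axis: the base margin is `|d|`,
applied symmetrically to both directions of the axis, and four candidate
margin sets are formed at offsets {-0.5, 0, +0.5, +1.0} x sigma. Every
component is clamped to [1.5, 5.0] mm: the floor reflects irreducible
radiation/mechanical isocenter coincidence uncertainty, the cap the clinical
guideline. With vanishing displacement and uncertainty all four sets collapse
to the 1.5 mm floor — the digital-twin plans then differ from the clinical
plan only by margin size.

Training pairs are sequential: features of each image predict the relative
CTV position on the *next* fraction (planning CT to first CBCT, CBCT *k* to
CBCT *k+1*). For held-out evaluation the planning-CT features predict each
fraction, which is exactly how the workflow queries the model at fraction 1.

## The surrogate plan engine

The real system behind this workflow is a commercial TPS: Monte-Carlo proton
dose on corrected CBCT plus a minimax robust optimizer. Neither is
reproducible in an open package, and neither is the scientific claim here.
The surrogate engine is therefore a deliberately simple geometric stand-in
that preserves the properties the workflow logic depends on:

* the margin-expanded CTV receives the full prescription (RBE-weighted Gy,
  constant RBE 1.1 folded into the prescription);
* outside the expanded target the dose holds a 2 mm full-dose shoulder and
  then falls off sigmoidally with an 80-20 penumbra width of 5 mm (both
  configurable). The shoulder models the fact that a robust optimizer keeps
  prescription coverage *at* the scenario-shifted target edge, not strictly
  inside it; without it, half-voxel rasterization noise at the target surface
  shows up as spurious worst-case cold spots;
* the 21 robustness scenarios (nominal + 6 cardinal shifts, each using its
  own direction's margin, crossed with range scales 1 and 1 +/- 3.5%) are
  enumerated for every plan, and the worst-case shifted-CTV D98 is checked
  against 95% of prescription; scenario doses are evaluated by trilinear
  interpolation of the distance map so the check is not quantized to whole
  voxels. The range scale acts as a falloff-distance multiplier — a cheap,
  explicitly non-physical proxy for proton range scaling;
* four beams (50, 300, 90, 270 degrees; weights 15/15/35/35%) are carried as
  metadata; the default dose model is isotropic.

Because dose is a monotone function of distance to the expanded target,
larger margins always produce pointwise larger dose — the monotonicity that
makes "smaller margins spare organs at risk" hold by construction, as it does
for real plans in aggregate.

Treatment-day evaluation emulates bony image guidance: the fraction anatomy
is rigidly translated so its femoral bounding-box center matches the planning
image's, then the plan's stored dose grid is read against the aligned
structures. Residual CTV displacement relative to the femora is exactly what
the margins must absorb. No rotation and no deformation are modeled, matching
the translation-invariant feature design.

## Metrics and scoring

Dose-volume metrics use the step (sorted-voxel) convention without
inter-voxel interpolation, reproducible across libraries to half a voxel
volume: Vx as % of structure or cc, Dx from the cumulated sorted voxel doses,
Dmean, and D0.03cc as the minimum dose of the hottest 0.03 cc. The dose
falloff metric D2cm is the maximum dose among *body* voxels at >= 20 mm from
the evaluation volume V (CTV expanded 5 mm, 3 mm posteriorly); restricting to
the body avoids scoring air. The Paddick conformity index is
TV_PIV^2 / (TV x PIV), defined as 0 when the prescription dose is reached
nowhere. Percent-of-prescription metrics use the CTV prescription (26 Gy)
even for boosted plans; the hot-spot constraint for the boosted trial is
checked in Gy against 110% of the boost prescription, since the boost region
legitimately exceeds 110% of the CTV prescription.

The plan-quality score sums 12 piecewise-linear scoring functions, one per
metric, each with a hard zero beyond its failure threshold. The CTV V100
function is fully pinned by its published anchor behaviour: 0 below 90%
coverage, then 2.0 points per percentage point from 15 points at 90% to a
35-point cap at 100% (so 98.07% scores 31.14 and 98.59% scores 32.18). The
remaining eleven functions are *package defaults*, linear ramps from 10
points at the ideal value to 0 at the trial's constraint limit; no published
rubric exists for them, so they are marked as defaults and fully overridable
through a JSON configuration. Totals are consequently configuration-relative:
they rank plans for the same patient and fraction, and are never compared
against published absolute totals.

Constraint checking follows the trial protocols with strict inequalities
(bladder V14.6 < 15 cc / V20.8 < 5 cc for the standard arm; relaxed bladder
limits, rectum V22 and urethra D0.03cc/D10% limits for the boosted arm).

## The two-fraction workflow

Fraction 1: five plans are built on the planning CT — the clinical plan with
constant margins and four digital-twin plans at the sigma offsets — then
evaluated on the first treatment CBCT and the highest total score selected.
Ties prefer smaller mean margins (less healthy tissue dose), then the
clinical plan, then pool order. Fraction 2: five new plans are built on the
first CBCT, pooled with the five carried plans (ten candidates), evaluated on
the second CBCT, and selected. Finally each selected plan contributes half
its course dose; the two half-doses are summed on the planning frame after
femoral alignment and scored against the planning anatomy. The non-adaptive
reference course for comparison delivers the clinical plan at both fractions.
Cohort comparisons use the exact two-sided paired Wilcoxon signed-rank test
(the design is paired per patient; identical samples return p = 1 and zero
differences are dropped, the standard signed-rank conventions).

Accumulating the two fraction doses by rigid femoral alignment is a modeling
choice: without deformable registration there is no unique way to sum doses
delivered to two different anatomies, and the translation-sum convention is
the one consistent with the rest of the package.

## The synthetic cohort

Because the institutional imaging behind this workflow is not distributable,
the package ships a generator that emulates its geometry: analytic shapes
rasterized on a 2 mm grid over a 240 x 192 x 200 mm field of view (wide
enough for adult femoral separation; a narrower default would clip the
femoral heads). Per patient: a 30-50 cc ellipsoidal CTV with a thin urethra
carved out (urethra-sparing convention), a bladder of 150-260 cc with an
inferior bladder-neck cap abutting the CTV, a posterior rectal tube separated
from the CTV by a 3-8 mm hydrogel-spacer gap, femoral heads of 20-28 mm
radius whose size co-varies with pelvic width (allometric scaling — skeletal
dimensions are correlated in real anatomy, and without that correlation the
femoral-box height would be an unlearnable free nuisance in the z-axis
regression target), and an elliptic body outline.

Fraction anatomies share the femoral geometry; the prostatic block (CTV, GTV,
urethra, bladder neck) is rigidly displaced per fraction. The motion model is
linear-Gaussian: a systematic per-patient drift proportional to the deviation
of the planning-day relative CTV position from a cohort reference (patients
whose prostate sits unusually relative to the bony anatomy drift more — which
is exactly the signal the features carry), plus per-fraction Gaussian noise
with a patient-specific amplitude. Posterior motion is truncated at the
spacer gap, which is the physical function of the hydrogel. Displacement
draws are rejection-sampled to the 2.1-13.2 mm planning-to-fraction COM-shift
band, the range the framework is intended to operate over; the band is
enforced on the continuous draws so generator behaviour does not depend on
grid resolution, and realized shifts are voxel-quantized (up to half a voxel
diagonal of wobble).

What the generator does *not* emulate: CT/CBCT intensities, deformable organ
motion, contouring variability, rotations, and real dosimetry. Tests passing
on this cohort therefore demonstrate that the pipeline's logic — feature
extraction, margin learning, scenario enumeration, scoring, selection — is
correct and internally consistent, not that the surrogate dosimetry predicts
clinical dose distributions.

## Problem sizes and numerical choices

The default study conditions are 40 patients (30 training, 10 demonstration)
with 5 fraction anatomies each, giving 150 sequential training pairs and 50
held-out planning-to-fraction predictions; the demonstration trial treats the
10 held-out patients end to end. On one CPU the cohort builds in about 40 s,
the margin model fits in a few seconds and the full trial runs in under two
minutes. Degenerate inputs are handled explicitly: empty masks error, zero
margins return the identical mask, zero-sigma predictions collapse the four
margin sets onto one (the pool keeps its fixed cardinality), all-below-range
scoring inputs score zero, and the max-separation pair breaks ties toward the
lowest indices. The arccos argument in the angle feature is clamped to
[-1, 1]; Cholesky factorizations carry a 1e-8 jitter.

Known limitations worth restating: the surrogate dose engine is geometric,
so absolute organ-at-risk volumes and scores are only meaningful relative to
each other; the z-axis of the margin model is the hardest to learn because
the reference-vertex convention folds the femoral-box height into the
target, and its recovery margin on the default cohort is small; and the
eleven non-anchored scoring functions are package defaults awaiting an
institutional rubric.
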