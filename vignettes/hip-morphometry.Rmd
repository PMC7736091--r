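---
title: "Measuring hip development from traced contours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hip development from traced contours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipmorph)
```

## The measurement model

`hipmorph` measures three radiographic indices of hip development —
the Tönnis angle, the Sharp angle and the centre-edge (CE) angle of
Wiberg — from manually traced bone contours on an AP pelvis
radiograph. The package deliberately begins *after* the manual steps:
its inputs are, per hip, an acetabular arc polyline (outer rim to the
bottom of the acetabular fossa), a femoral arc polyline (head to
neck), a marked sourcil medial point and a teardrop inferior point,
in pixel coordinates with the image convention (origin top left, y
increasing inferiorly). Automatic contour segmentation is out of
scope: at clinical image quality it remains unreliable for the
acetabulum, which is precisely why semiautomatic systems of this
design exist.

All directional notions are defined relative to the **pelvic frame**:
line a connects the inferior edges of the two teardrops, the superior
direction is its perpendicular pointing cranially, and each hip's
lateral direction points along line a away from the pelvic midline.
Working in this frame, rather than against the image axes, makes every
measurement invariant to in-plane rotation of the radiograph; the
package verifies this property under random rigid motions and uniform
scaling (tolerance 1e-6 degrees).

### Landmarks

The femoral head centre is found geometrically, not photometrically:
three well-spread points on the femoral arc determine it as a
circumcircle —

1. the arc vertex extremal in the superior direction,
2. the arc vertex extremal in the lateral direction,
3. the intersection of the segment from point 2 to the teardrop with
   the arc (the medial head point); when the chord crosses the
   polyline more than once, the crossing closest to the teardrop is
   used.

The circumcircle of the three points is the head estimate; a
least-squares fit is *not* used as the primary estimator, but the
median distance of the arc's head-region vertices (within 1.5 fitted
radii of the centre) from the fitted circle is checked, and a warning
is raised when it exceeds 5% of the radius — on real traces this
flags a poorly circular head or badly placed landmarks.

The acetabular lateral margin is the more lateral of the two
acetabular-arc endpoints; if their lateral projections differ by less
than 1 px the endpoint rule is ambiguous and the extremal vertex of
the whole arc along the superolateral diagonal is taken instead. One
anchor point serves as both the lateral sourcil edge (Tönnis) and the
acetabular rim (Sharp, CE): standard radiographic practice does not
distinguish them, and a single anchor keeps the three indices
mutually consistent.

### Angles and sign conventions

With sourcil medial M, lateral margin P, teardrop T, head centre C,
lateral unit l and superior unit s:

- Tönnis = atan2((P−M)·s, (P−M)·l) — positive for an upsloping
  sourcil, negative for a downsloping one;
- Sharp = the acute angle between P−T and line a, unsigned in
  (0, 90);
- CE = the angle between P−C and the pelvic vertical, positive when P
  lies lateral to the vertical through C.

Clinical series report negative minima for Tönnis and CE, so signed
conventions are required even though the classical definitions leave
them implicit; the ones above make dysplastic hips (upsloping
sourcil, uncovered head) positive-Tönnis and low-CE.

Whether the CE "vertical" should be the image column direction or the
perpendicular to line a is genuinely ambiguous in the clinical
literature; the package defaults to the pelvic perpendicular (it
removes rotation artifacts and is consistent with how the other two
indices use line a) and exposes `vertical = "image"` in `ceAngle()`
and `measurePelvis()` for the literal reading. On an unrotated,
well-positioned radiograph the two agree.

Anatomical sides: a standard AP view shows the patient's left hip at
larger image x. Annotations carry explicit side labels;
`buildFrame()` infers sides from x-order when they are absent (which
also makes it invariant to argument order) and accepts an explicit
assignment, needed for images rotated by 45 degrees or more where
x-order stops being diagnostic.

### Classification

Thresholds follow the clinical wording with strict inequalities:
Tönnis dysplasia iff > 10° (10.0 itself is normal), Sharp dysplasia
iff > 45°, CE dysplasia iff < 20° with borderline on the closed
interval [20, 25]. Folding borderline and dysplasia into "abnormal"
is equivalent to a single dichotomous cut at CE ≤ 25, consistent with
ROC-selected operating points falling just below 25 in validation
cohorts.

The SVM uses a polynomial kernel of degree 2 with penalty C = 0.3 and
otherwise library defaults (coef0 = 0, gamma = 1/(n_features ·
var(X)), the "scale" convention), trained on the three raw angle
values per hip. The features are deliberately *not* centred: with
coef0 = 0 a degree-d polynomial kernel satisfies K(−u, v) =
(−1)^d K(u, v), so for even d the decision function cannot tell a
feature vector from its negation — centred, roughly symmetric
two-cluster data becomes unseparable — whereas raw angle vectors live
well away from the origin and separate cleanly. Since no train/test protocol is standard for
this configuration, the package exposes stratified 5-fold
cross-validation with a fixed seed alongside the fit-on-all model;
which angles feed the classifier is configurable by passing any
feature table with the three angle columns.

### Evaluation statistics

All table statistics are closed-form ratios of integer counts,
rounded only at report time (percentages to one decimal, κ to three).
Two choices deserve a note:

- **McNemar**: the exact two-sided binomial test on the discordant
  counts is the default at every table size, with the
  continuity-corrected chi-square available by flag. On published
  paired tables of this size the exact test reproduces the reported
  p-values where the corrected chi-square does not exactly.
- **Three-class symmetry**: clinical reports often say "McNemar" for
  k = 3; the package implements Bowker's generalisation
  (Σ (n_ij − n_ji)²/(n_ij + n_ji), one df per discordant pair, pairs
  with zero sum contributing nothing and dropping a df) and delegates
  to the exact McNemar when k = 2.

ROC thresholds are the midpoints between consecutive distinct scores
plus ±∞ — consistent with reported operating cuts falling between
observed values — with trapezoid AUC (equal to the Mann–Whitney
concordant-pair fraction, a property the test suite checks on random
score sets) and Youden-index threshold selection, ties broken toward
higher specificity. For the CE angle, where *low* values indicate
disease, `orientation = "lower_is_positive"` negates scores
internally and reports thresholds on the original scale.

## The phantom generator

The system under test consumes contours, so the generator inverts the
angle definitions analytically instead of synthesising images. Per
hip, in the (l, s) basis anchored at the teardrop T, with head radius
R (default 25 px):

- rim P = T + 2R (cos Sharp, sin Sharp) — the teardrop-to-rim
  distance of 2R matches typical adult proportions;
- centre C = P − 0.9R (sin CE, cos CE) — the rim sits near the head
  circle, so the rim–centre distance is just under R;
- sourcil medial M = P − 0.8R (cos Tönnis, sin Tönnis) — a sourcil
  chord of 0.8R;
- the femoral arc is sampled on the circle (C, R) from 170° medial of
  superior to 100° lateral, always including the exact superior and
  lateral points; the medial reach matters because the chord from
  the lateral head point to the teardrop exits the circle near −161°
  in the steepest clinical configurations (Sharp ≈ 56°, CE ≈ 47°);
- the acetabular arc is a polyline from P through M down to a point
  just above the teardrop.

An earlier design placed C at a fixed offset from T and derived P as
the intersection of the Sharp ray from T with the CE ray from C; that
construction degenerates when Sharp + CE approaches 90°, which lies
*inside* the clinically observed box, so the rim-first construction
above was adopted — it is exact for every target in the box.
Construction still fails, with a dedicated error, when the targets
would put the head centre on or below line a or the teardrop inside
the head circle (possible only far outside clinical ranges).

Because P and M are exact polyline vertices, the Tönnis and Sharp
angles are recovered exactly; only the CE angle carries the error of
refitting the head circle through polyline-sampled points, bounded by
the chord sagitta (≈ 0.007 px at the default 100-point sampling,
giving CE errors below 0.01°). The test suite checks recovery within
0.1° for 500 random targets over the clinical ranges (Tönnis
[−8, 33], Sharp [30, 56], CE [−4, 47]), and recovery of the
generating circle to 1e-6 px at 20001-point sampling.

Optional Gaussian jitter (`jitterSd`, seeded) perturbs every contour
vertex. Sensitivity at `jitterSd = 1` px is dominated by the
single-vertex landmarks: with a 20 px sourcil chord, 1 px of noise on
the rim vertex alone contributes ≈ 2.3° to the Tönnis angle in
expectation, so the regression test bounds the mean absolute angle
error at 3° (and the head-centre error at 2 px). On real
high-resolution radiographs the same absolute tracing noise acts over
levers an order of magnitude longer; the phantom's 25 px head radius
makes this a deliberately harsh noise regime.

## The cohort simulator

`simulateCohort()` emulates the *statistical* shape of a paired
physician/CAD validation cohort rather than its image content. Latent
per-hip angle triples are drawn from a trivariate normal whose means
and total SDs default to a published 248-hip cohort (Tönnis
8.490 ± 6.510°, Sharp 39.897 ± 4.178°, CE 28.129 ± 8.090°), with
inter-angle correlations Tönnis–Sharp +0.4, Tönnis–CE −0.6, Sharp–CE
−0.5 — clinically plausible values chosen here, not published ones,
and configurable. Physician and CAD observations add independent
reader noise calibrated analytically: latent SD = total SD·√0.9 and
noise SD = total SD·√0.1 give observed per-method SDs equal to the
published totals and corr(physician, CAD) = 0.9 in expectation, the
regime reported for well-validated semiautomatic systems. The
calibration is closed-form and was fixed before any test was run.

What the simulator does **not** emulate: systematic inter-method bias
(published CAD means differ from physician means by up to ≈ 1.3°),
non-Gaussian tails, per-patient correlation between the two hips, and
any dependence of reader noise on the angle value. Threshold-label
confusion tables derived from the simulator therefore match the
published tables in structure (nonzero discordants, realistic
marginals) but not cell-for-cell; tests assert the structural
properties only. The published headline correlations and AUCs cannot
be recomputed exactly — the per-hip raw measurements are not public —
which is why the validation strategy combines the published *count
tables* (reproduced exactly by the evaluation module) with
property-based checks on simulated data.

## Numerical choices

- Collinearity: three points are degenerate when the triangle area is
  below 1e-9 × span², span the largest pairwise distance.
- Segment–polyline intersections within 1e-6 px of the segment start
  are discarded (guards against re-finding a start point lying on the
  polyline); duplicates from shared vertices are merged at the same
  tolerance.
- Extremal-vertex ties (projections within 1e-9 × span of the
  maximum) break toward the larger projection on the clockwise
  perpendicular of the direction — deterministic, so identical input
  bytes give identical landmarks.
- `vertexAngle()` clamps the normalised dot product to [−1, 1] before
  `acos`.
- Degenerate inputs raise typed conditions
  (`hipmorph_degenerate_geometry`, `hipmorph_landmark_extraction`,
  `hipmorph_phantom_construction`, `hipmorph_schema`,
  `hipmorph_undefined_metric`, `hipmorph_input`) so callers can
  branch without parsing messages; one failing hip never aborts the
  contralateral measurement.

Problem sizes in the standard validation runs — 500 noise-free
phantoms for round-trip, 300 jittered phantoms for the noise
regression, 200 score sets for the AUC cross-check, cohorts of 248
(calibrated) and 500 (clean, for the SVM) — keep the full suite
comfortably under a minute while leaving the Monte-Carlo bounds far
from their thresholds.

## Known limitations

- Raw polylines are used as given: no smoothing or spline resampling,
  so measurement quality is bounded by tracing quality (by design —
  the tracing protocol is the clinical input).
- The sourcil medial point is a manual input; the package cannot
  detect a mislabelled one beyond a bounding-box sanity check
  (`hipmorph.sourcilMargin` option, default 25 px).
- Osteophytes and dysmorphic heads violate the circular-head
  assumption; the plausibility warning flags but does not correct
  them.
- The evaluation module reproduces published tables and implements
  the standard statistics, but which variant a given clinical report
  used (e.g. its McNemar flavour) can only be inferred from numeric
  agreement.

```{r session}
sessionInfo()
```
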