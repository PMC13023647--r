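---
title: "Methods: four-chamber-view biometry from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-chamber-view biometry from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourcv)
```

## The measurement model

`fourcv` operates strictly downstream of segmentation: its input is a set
of five co-registered binary rasters of a fetal four-chamber view — heart,
ventricular septum, whole thorax (the filled thoracic cross-section),
thorax (the same region minus the spine), and descending aorta. Everything
the package reports is a deterministic geometric function of those rasters.
The coordinate convention is the image one throughout: 0-based pixel
indices, x rightward, y downward, a pixel located at its centre. All
ratios and angles are invariant to isotropic pixel spacing, so no physical
calibration is required.

The landmark chain is:

1. **Spine centroid S.** The spine is not segmented directly; it occupies
   the posterior hollow of the thorax label. S is recovered by filling the
   convex envelope of the thorax foreground, subtracting the thorax, and
   taking the centroid of the largest connected residual.
2. **Line RS.** The line through S that bisects the whole-thorax area; R is
   its crossing with the thoracic outer contour farthest from S. S→R runs
   posterior → anterior and defines the anteroposterior reference of the
   image, tilted by an angle θ from image-vertical.
3. **Septal line.** The principal (orthogonal least-squares) axis of the
   ventricular septum. Orthogonal rather than ordinary regression because
   a septum can be arbitrarily close to vertical, where regressing y on x
   is ill-posed; the principal axis is rotation-equivariant.
4. **Derived points.** I = septal line × line RS; V = septal-line crossing
   of the thoracic contour nearer the septum centroid (an apex surrogate);
   A = crossing of the ray S → descending-aorta centroid with the contour
   beyond the aorta (an aorta surrogate on the chest wall).

From these: CTAR is the raw foreground ratio heart/whole-thorax (no
elliptical approximation); the cardiac axis is ∠RIV in degrees, measured
identically for left- and right-pointing hearts; the apex side is the sign
of the cross product of S→R with S→V; laterality compares the sides of V
and A relative to line RS; and the cardiac-position landmark point P is the
septal-line crossing of the cardiac circumference opposite the septum,
expressed in the thorax-relative frame described next.

## The point-P frame and its unit

Point P is translated by the whole-thorax centroid O′, rotated by −θ so
the y′ axis runs along line RS, y′-flipped so anterior is positive, and
scaled by unit lengths derived from the two thoracic chords through O′
(B1B2 perpendicular to line RS, A1A2 along it). The frame divides each
chord into `pointp_divisions` equal parts (default 8), i.e. one unit is an
eighth of the chord and a semi-chord spans four units; the reference box
for a normal position is 0 ≤ g\_x ≤ 2, −1 ≤ g\_y ≤ 1, with g\_x folded to
the apex side.

Two interpretation decisions are deliberate and worth recording:

* **Unit length = chord/8.** The alternative convention of a half-chord
  unit makes the reference box span the entire thorax, so no physically
  realisable cardiac position could ever be flagged — the box would bind
  only for a point outside the chest wall. With the chord/8 unit the box
  covers a central region about one half semi-chord wide laterally and one
  quarter of the anteroposterior chord, which both discriminates and
  matches the intended reading of dividing the reference chords "into
  eight equal parts". The divisor is still a configuration knob
  (`pointp_divisions`) for sensitivity analysis.
* **Folding g\_x.** A piecewise sign-preserving definition of g\_x
  degenerates to the identity, while the one-sided box 0 ≤ g\_x ≤ 2 only
  makes sense for a coordinate measured toward the apex side. g\_x is
  therefore |p′\_x|: mirror-image anatomy maps onto itself and the box is
  apex-side-relative.

## Screening rules

Normal ranges follow obstetric screening guidelines: CTAR < 35% (so
exactly 0.35 is abnormal — the closed boundary is on the abnormal side),
cardiac axis 45° ± 20°, point P inside the box above. Two further flags
are categorical: an orientation mismatch (inferred vs examiner-declared
presentation) and laterality inversus. The overall call is positive if
*any* flag is raised — a right aortic arch presents only through the
laterality relation, and triage should not miss it — while the ordinal
score used for ROC analysis counts only the three biometric parameters
(CTAR, axis, point P) so that with/without-parameter comparisons stay
transparent. Video-level aggregation averages the continuous parameters
over a video's extracted images (typically two) and takes majorities for
categorical ones, with ties resolved toward abnormal; a patient with no
extractable four-chamber view is screened positive outright. All ties and
degeneracies resolve toward sensitivity, the cost asymmetry of a triage
step whose positives are referred to a secondary examination, not treated.

Indeterminate laterality (missing or degenerate aorta mask) leaves the
flag unset and is noted in the result rather than counted abnormal: an
absent structure is an extraction problem, not evidence of situs inversus.

## Numerical choices

* **Area bisection.** The balance of a candidate line is the signed count
  of foreground pixel centres on each side. A 1° coarse sweep over [0°,
  180°) (on a regular pixel subsample for large rasters) brackets the
  crossing; a full-resolution fine sweep of the ±1.5° neighbourhood at
  0.05° resolution then selects the best-balanced angle, breaking ties
  toward the smallest angle to image-vertical. Success requires the
  residual imbalance ≤ 0.5% of the area; above 5% the operation fails
  loudly (`bisect_failure`) instead of returning a bad line.
* **Contours.** Marching squares (`grDevices::contourLines` at level 0.5)
  on the largest 8-connected component, followed by one vertex-averaging
  pass: the raw staircase inflates the perimeter of a smooth region by
  several percent, and averaging restores it at well under half-pixel
  vertex displacement. Line–contour intersections are deduplicated within
  0.5 px and ordered along the line.
* **Spine hollow.** Largest connected residual of (convex hull − thorax);
  residuals under 10 px are treated as rasterisation slivers, not hollows,
  so anti-aliased or slightly concave boundaries do not fabricate a spine.
* **Degenerate inputs.** Isotropic septum (eigenvalue gap below 1e-6) →
  degenerate-fit error; V on line RS within 0.5 px → indeterminate side;
  septal line parallel to line RS → the axis is the angle between the two
  directions (0 in the exact limit) since I does not exist; the angular
  laterality identity uses ε = 1° for its equality test, the side-sign test
  being authoritative.
* **Validation tolerance.** Containment (heart ⊆ whole thorax, septum ⊆
  heart) allows 2% stray pixels because real segmentations leak at
  boundaries; beyond that, validation reports a violation and measurement
  refuses to run.

## The phantom generator

The phantom emulates exactly the geometry the measurements assume: a
rotated elliptical whole thorax with a posterior spine disk cut out of the
thorax label, an interior heart ellipse whose septal axis carries a septum
strip from the crux toward the apex, and a small descending-aorta disk
beside the spine on a chosen side. Rasterisation is a pixel-centre-inside-
region test with no anti-aliasing, so areas are exact pixel counts, rasters
are platform-stable, and cohorts are bit-reproducible from a seed. The
heart is scaled to the target CTAR by bisection against the rasterised
whole-thorax count (rasterisation quantises areas), keeping its basal
anchor fixed.

Two design points:

* **Heart placement is solved backward from point P.** The spec of a
  phantom gives the target point-P location (or, alternatively, a
  heart-centre offset); the heart centre is then placed one septal
  semi-axis apex-ward of that anchor. This makes the ground truth for the
  hardest parameter exact by construction.
* **The heart may be broader than it is long.** At realistic CTAR
  (0.21–0.31) a heart strongly elongated along the septal axis cannot both
  fit inside the thorax and keep its basal wall inside the point-P
  reference box; the generator therefore allows the semi-axis
  perpendicular to the septum to exceed the septal one
  (`heart_axis_ratio`, default 1.15). The septum strip still lies along a
  principal axis of the heart, so the septal line fit is unaffected.

Normal cohort draws stay inside every normal range with margins of at
least twice the corresponding measurement tolerance; abnormality presets
(cardiomegaly CTAR ≥ 0.40, axis deviation ≤ 15° or ≥ 78°, dextrocardia,
inversus, posteriorly displaced point P ≥ 0.5 units outside the box) sit
outside by the same margin, so classification suites are deterministic
rather than borderline. A draw that lands geometrically infeasible is
redrawn from the same seeded stream. The `perturb_masks` module emulates
segmentation imperfection with seeded boundary flips and foreground
dropout for robustness testing.

What the phantom does **not** emulate: ultrasound appearance (speckle,
acoustic shadows, B-mode texture), systole/diastole differences, septal
curvature, chamber-level anatomy, or correlated segmentation failure modes
of a real network. Tests passing on phantoms therefore validate the
geometry and decision logic, not segmentation quality on clinical images.

## Test problem sizes

The test and acceptance suites use: 200 seeded normal phantoms at 256² for
parameter recovery (mean absolute error bounds: CTAR 0.02, axis 3°, point-P
components 0.15 units); 50 phantoms per abnormality preset for
classification determinism; 20 two-disk fixtures for the bisection oracle
(agreement within 0.2° of an exhaustive 0.05° sweep); 20 phantoms for the
scale (256² → 512²), quarter-turn and mirror invariances; and 100 phantoms
for the laterality-rule consistency property. The bundled CHD cohort
worked example is pure screening arithmetic over published summary counts
(22 patients, 7 non-extractable, two images per extractable video) and is
labelled a synthetic reconstruction: per-image values are carriers of the
printed counts, not measurements.

## Known limitations

* The spine must produce a recoverable hollow in the thorax label; a
  thorax segmented with the spine filled in defeats the convex-envelope
  construction (`no_hollow` error).
* V and A are chest-wall surrogates for the apex and aorta, not the organs
  themselves; very oblique septa with far-posterior intersection points
  inflate the leverage of small septal-fit errors.
* The ordinal ROC score has only four levels; with deterministic phantom
  cohorts it saturates, which is expected of the design rather than
  evidence about clinical discrimination.
* Laterality cannot distinguish right from left isomerism — it only
  detects apex/aorta side disagreement.
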