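# fourcv

Automated biometry and screening of the fetal **four-chamber view (4CV)**
from per-structure segmentation masks.

Prenatal screening for congenital heart disease relies on a handful of
quantitative cues in the 4CV — is the heart too large, is its axis rotated,
does it sit where it should, are the apex and the descending aorta on the
same side of the chest? Measuring these by hand is operator-dependent.
`fourcv` implements the measurement stage of a fully automated pipeline:
given binary masks of five anatomical structures (heart, ventricular
septum, whole thorax, thorax, descending aorta) — in practice the output of
a segmentation network, here also producible by a built-in analytic phantom
generator — it computes the screening parameters, classifies them against
guideline normal ranges, and aggregates image → video → patient screening
calls. It is aimed at researchers developing or evaluating automated fetal
cardiac screening who need a transparent, testable reference for the
geometry downstream of segmentation.

## What is measured

With `S` the spine centroid (recovered as the centroid of the posterior
hollow of the thorax mask via its convex envelope), and the **line RS** the
line through `S` that bisects the whole-thorax area (`R` is its crossing
with the thoracic contour farthest from `S`):

* **CTAR** (cardiothoracic area ratio) — pure pixel counting,
  `CTAR = |heart| / |whole thorax|`; normal `< 35%`.
* **Cardiac axis** — the septal line is the orthogonal-least-squares
  principal axis of the ventricular septum; with `I` its intersection with
  line RS and `V` its thoracic-contour crossing nearer the septum, the axis
  is `∠RIV = arccos( (IR·IV) / (|IR||IV|) )`; normal `45° ± 20°`.
* **Apex side / presentation** — the sign of the cross product of `S→R`
  with `S→V` places the apex left or right of line RS, which maps to an
  inferred cephalic or breech presentation; a mismatch with the examiner's
  declared presentation flags abnormal orientation.
* **Laterality** — with `A` the contour crossing of the ray from `S`
  through the descending-aorta centroid, apex and aorta on the same side of
  line RS is situs *solitus*; opposite sides (*inversus*, as in right
  aortic arch) is abnormal. The equivalent angular identity
  `∠VSA < ∠RSV + ∠RSA` (normal) vs `∠VSA = ∠RSV + ∠RSA` is kept as a
  consistency check.
* **Point P** (cardiac position) — the crossing of the septal line with the
  cardiac circumference opposite the septum, expressed in a thorax-centred
  frame: translate by the whole-thorax centroid `O′`, rotate by the thorax
  tilt `θ`, flip the y′ axis, and scale by unit lengths `d_x = |B1B2|/8`,
  `d_y = |A1A2|/8` (the thoracic chords through `O′` divided into eight
  parts); `g_x` is folded to the apex side. Normal box
  `0 ≤ g_x ≤ 2, −1 ≤ g_y ≤ 1`.

A patient screens **positive** when any parameter is abnormal or when no
4CV could be extracted from the video at all.

## Worked example

```r
library(fourcv)

ph  <- generate_phantom(phantom_spec(ctar_target = 0.28, heart_axis_angle = 50,
                                     thorax_rotation = 12, source_id = "demo"))
rec <- measure_biometrics(ph$mask_set)
rec
#> <biometric_record> demo
#>   CTAR          28.0%
#>   cardiac axis  50.2 deg
#>   apex side     left_of_RS (cephalic)
#>   laterality    solitus
#>   point P       (0.39, -0.44)

classify_parameters(rec, declared_presentation = "cephalic")
#> <screening_result> level=image overall=negative
#>   abnormal flags: none
```

The phantom was built with true CTAR 0.28, true axis 50°, and true point P
(0.40, −0.45); the measured values above are recovered from the rasterised
masks alone. CTAR sits below the 35% threshold, the axis inside 45° ± 20°,
point P inside the reference box, the inferred presentation matches the
declared one, and the apex and aorta share a side — so every flag is clear
and the image screens negative.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/fourcv.R phantom --preset normal -n 2 --seed 4 --out demo
Rscript inst/cli/fourcv.R measure --masks demo/phantom_001 --out demo/rec.json
Rscript inst/cli/fourcv.R screen  --cohort cohort.jsonl --out screen_out --roc
```

## Layout

* `R/mask_io.R` — mask-set PNG/JSON reading, writing, validation
* `R/geometry.R` — raster/planar geometry primitives
* `R/biometrics.R` — landmark construction and the screening parameters
* `R/screening.R` — normal ranges, flags, image/video/patient aggregation
* `R/phantom.R` — analytic phantom generator with ground truth
* `R/evaluation.R` — Dice, MAE, ROC/AUC, Youden point
* `R/cli.R`, `inst/cli/fourcv.R` — pipeline entry points
* `vignettes/fourcv-methods.Rmd` — the methods notes: model, parameters,
  numerical choices, phantom design, limitations
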