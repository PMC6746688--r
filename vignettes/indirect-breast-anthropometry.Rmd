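---
title: "Indirect breast anthropometry: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect breast anthropometry: model, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photanthro)
```

## The measurement model

Direct breast anthropometry — tape measure and skin marker on the patient —
is the clinical gold standard, but it is operator-dependent, it forces the
tape to follow chest curvature, and it requires physical contact. Indirect
anthropometry replaces the tape with digital markers on a frontal
photograph. Two ingredients make pixel coordinates metric and
posture-independent:

1. **Scale calibration.** A rigid reference unit of known length (2 cm by
   protocol) lies flat on the chest, perpendicular to the camera axis. Its
   two marked endpoints give `pixels_per_cm`, and any pixel distance divided
   by that scale is a centimetre value. Because the scale is carried by the
   photo itself, no focal length, camera distance or sensor information is
   needed, and photographs taken in non-standardised conditions remain
   comparable.

2. **The medial line as body-fixed reference frame.** The axis through the
   sternal notch (SN) and the umbilicus (UMB) defines the patient's midline.
   Perpendicular distances to this line give the midline–nipple and
   IMFA–midline measurements; *levels* are scalar projections onto the unit
   axis, with zero at SN and positive towards UMB. A level difference
   (nipples, fold apices, upper poles) is the difference of two projections,
   converted to cm.

All outputs are Euclidean constructions from ratios of pixel lengths, so the
panel is provably invariant under any rigid motion of the image content and
under isotropic rescaling as long as the reference segment rescales with it.
The test suite asserts both invariances end to end.

### Why orthogonal projection, not image-horizontal projection

The protocol's description of level measurement is a "horizontal projection
onto the midline". On a perfectly upright photo the two readings coincide.
On a rolled camera they do not: projecting along the image x-axis mixes
camera orientation into an anatomical quantity. Since the whole point of the
method is robustness to non-standardised photographs, this package projects
**orthogonally onto the body's midline axis**, which is what a tape measure
against the sternum does and what makes level differences roll-invariant. An
implementation that projects along the image axis would differ on tilted
photos; this is the one deliberate point where behaviour is fixed by
geometry rather than by the (ambiguous) original description.

### Two-photo binding

Ptotic breasts hide the inframammary fold and upper breast border on a
relaxed photo, so those landmarks are marked on a second, breasts-lifted
photo. Marking the medial line (SN and UMB) on *both* photos gives two point
correspondences, which determine a unique 2-D similarity transform
(rotation θ, isotropic scale σ, translation t). We solve it exactly in the
complex plane: with midline endpoints `s₁, s₂` (secondary) and `t₁, t₂`
(primary) as complex numbers, `a = (t₂ − t₁)/(s₂ − s₁)` and `b = t₁ − a·s₁`
give `z′ = a·z + b`, i.e. σ = |a|, θ = arg a. A line alone would leave scale
and along-axis translation undetermined, which is why both endpoints must
correspond anatomically; this stronger, well-posed contract is a deliberate
design choice. Nipples are always taken from the relaxed photo (their
lifted position is not the clinical one); IMFA and UPA are taken from the
lifted photo whenever one is attached, and such values are flagged
`two-photo`.

If both photos carry their own calibration, the transform's scale factor is
cross-checked against the ratio of the two calibrated `pixels_per_cm`.
Disagreement beyond 5% (configurable) raises a **warning**, not an error:
lifting the breasts can genuinely change the chest–camera distance slightly,
so a hard failure would reject valid data, but silence would hide marking
errors.

## The 13-measurement panel and ratios

Level differences NLD, IMFLD, UPLD; midline distances MLN and IMFML (right
and left); chords SNN, IMFN, UPN (right and left). Internally level
differences keep their sign (right minus left, positive = right landmark
more inferior); the public panel reports magnitudes, matching clinical
reporting. Values are kept at full precision internally and rounded to
0.1 cm (tape-measure precision) only in human-readable reports.

A measurement is emitted iff all its landmarks are annotated; missing
optional landmarks (e.g. no UPA on a male subject) produce *absent* values,
never zeros. The lateral/medial breast borders (LB/MB) are not part of the
13-measurement list; they exist in the vocabulary solely because the
horizontal aesthetic ratio needs them, so that ratio is computed only when
they are annotated.

Ratios are plain normalisations: vertical `100·UPN/(UPN+IMFN)` against the
published 45:55 "most appealing" upper:lower reference, horizontal
lateral:medial against 40:60. Components always sum to 100.

## The reliability battery

* **Accuracy**: signed differences `d = digital − direct reference` pooled
  over subjects and sessions per (measurement, observer); MAD = mean |d|.
  The accompanying SD is, by default, the SD of the *signed* differences.
  The published summary tables are ambiguous here — several printed
  (MAD, SD) pairs (e.g. MAD 0.11, SD 1.38) are impossible for non-negative
  values — and only the signed reading is internally consistent. The SD of
  |d| is available via `sd_of = "absolute"`.
* **ICC**: the original validation never names its ICC form. The default
  here is **ICC(2,1)** — two-way random effects, absolute agreement, single
  measurement — for both the within-observer (sessions) and between-observer
  facets, because clinical interchangeability requires absolute agreement
  and both facets are naturally random samples. ICC(3,1) (mixed,
  consistency) is offered as an option. Confidence intervals use the exact F
  bounds for ICC(3,1) and the McGraw–Wong bounds with a Satterthwaite
  denominator df for ICC(2,1); the implementation was cross-checked against
  an independent reference implementation, and a frozen fixed-matrix oracle
  guards it in the tests.
* **SEM** `= SD·√(1 − ICC)`: measurement-error SD in cm; always ≤ SD, zero
  iff ICC = 1.
* **CV**: per subject, `100·sd/mean` over that subject's repeated values,
  averaged across subjects (one CV per measurement is what the published
  tables report); a pooled RMS variant is available behind a flag.
* **Bland–Altman**: differences vs pair means; bias ± 1.96·SD limits of
  agreement. Under normal errors the limits contain ≈95% of differences.
* **Effectiveness**: the share of MAD values strictly below the accepted
  1 cm deviation threshold for the thoracic region, over *all MADs
  supplied*. (The original report implies a denominator its text never
  explains; no denominator is hard-coded here.)
* **Interpretation bands**: Cicchetti (poor/fair/good/excellent at
  0.40/0.60/0.75) and the clinical scale (good at 0.75, clinical measure
  above 0.87), lower band edges inclusive.

Table output rounds cm to 2 decimals, ICC to 3 and CV to 1 — the published
format — but only when `round_output = TRUE`; estimation is full precision.
No multiple-testing correction is applied anywhere: the battery estimates
agreement, it does not test hypotheses.

## The synthetic world

The generator exists so the full pipeline — marking, calibration, two-photo
binding, panel, statistics — can be tested against known ground truth,
emulating the original validation design (10 subjects per sex group, 2
observers of different experience, 3 weekly sessions).

* **Subjects** start from a sex-type preset in a body-fixed cm frame (SN at
  the origin, SN–UMB 25 cm for the female preset). Preset magnitudes follow
  typical adult torso anthropometry; the female breast geometry was placed
  so the vertical pole ratio of the unperturbed preset sits near the 45:55
  aesthetic reference. Each landmark then gets independent Gaussian
  anatomical variation (default SD 1 cm) and any requested asymmetry
  offsets, so the ground-truth panel is known in closed form by
  construction.
* **Photographs** apply scale, roll and translation; default resolution is
  35 px/cm, a torso filling a typical consumer photo. An optional
  perspective *skew* coefficient (`x/(1+κy)` foreshortening, κ ≤ 0.05/cm)
  models a non-perpendicular camera; it is zero by default because the
  photographic protocol explicitly controls for it, and it exists to
  *quantify* the error of violating that protocol (panel error grows
  monotonically with κ, which the tests assert).
* **Observers** add a per-landmark systematic bias (drawn once per observer,
  SD 1 px/axis) plus i.i.d. click jitter (default SD 2 px/axis — at
  35 px/cm roughly 0.06 cm, the scale of careful cursor placement). The
  calibration endpoints are clicked too, so scale error propagates into
  every value, and because noise lives in pixel space, cm-error shrinks
  automatically with image resolution — mirroring the observation that
  accuracy is limited by pixel resolution.
* **References** default to exact ground truth (the simulated "direct"
  measurement); optional tape-measure noise can be added.

Everything is deterministic under a master seed (per-subject, per-observer
and per-session seeds are derived arithmetically, all below 2³¹).

What a green synthetic test does **not** establish: the generator has no
soft tissue, no skin extensibility, no curvature bias in its references, no
landmark-identification ambiguity (the dominant real error source for fold
apices on ptotic breasts), and no lens distortion. It validates the
*computational* pipeline exactly — geometry, binding, statistics — not the
human factors the original study measured; the published per-subject
accuracy values are not reproducible without the unpublished raw
photographs, and the package does not pretend otherwise.

## Numerical choices and degenerate inputs

* Coincident calibration endpoints, coincident midline endpoints,
  non-positive reference lengths and mixed photo frames are hard errors.
* ICC needs ≥2 subjects, ≥2 repeats, a complete design and non-zero total
  variance; a floating-point-negative residual sum of squares is clamped to
  zero, and with zero residual variance the ICC is exactly 1 with a
  degenerate CI.
* Ratio denominators of zero (both distances zero) are errors, not NaNs.
* Rigid-motion invariance is asserted to 1e-9 relative, geometry against
  brute-force formulas to 1e-12 — comfortably above double-precision noise
  for coordinates up to ~10³ px.
* Reports and SVG overlays are rendered with fixed-format, locale-free
  number formatting, so regeneration is byte-identical (asserted).

## Known limitations

Only frontal-view linear measurements: no volumes, contours, projection
(anterior-posterior) measurements or ptosis grading. The similarity
transform assumes the torso moves rigidly between the two photos; a subject
who twists between shots violates it. The skew model is a one-parameter
foreshortening, not a camera model. The published summary statistics shipped
with the package are numeric anchors for the statistics battery, not a
substitute for the unavailable raw validation data.
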