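---
title: "Methods: visual-field modelling, defect criteria and CNN screening in vfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual-field modelling, defect criteria and CNN screening in vfscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vfscreen` models Humphrey 24-2 white-on-white perimetry end to end: the
test-point geometry, normative deviation maps and their probability
categories, global indices, the clinical cluster criterion for a
glaucomatous field defect, a labelled simulator, compact convolutional
classifiers over the embedded maps, a printed-plate recognizer, and the
diagnostic statistics used to evaluate all of it. This vignette explains
the models and conventions, the tunable parameters, and the places where
a genuine design choice had to be made.

## The 24-2 geometry

The 24-2 pattern places test points at odd multiples of 3 degrees on a
6-degree lattice: rows at |y| = 21 hold x in {±3, ±9}; |y| = 15 adds ±15;
|y| = 9 adds ±21; the |y| = 3 rows additionally carry the nasal point at
x = −27. That yields 54 nominal points, of which the pair at
(x = +15, y = ±3) overlies the optic-nerve head (the physiologic blind
spot) and is excluded, leaving the 52 active locations every map in this
package is defined on.

All processing happens in a canonical right-eye frame (temporal = +x,
superior = +y); left-eye data are mirrored on ingestion so a single CNN
input convention serves both eyes. Contiguity is 8-connectivity on the
lattice (|Δx| ≤ 6 and |Δy| ≤ 6), the permissive reading of "contiguous";
4-connectivity and a hemifield restriction are available as options
because the original criterion is not explicit on either point. A
location is an *edge* location if it lies on the outer perimeter of the
pattern (the |y| = 21 rows, the x-extremes of each remaining row, and
the nasal x = −27 points). The active locations embed bijectively into
an 8 × 9 grid (rows y = 21…−21, columns x = −27…21), which is the
spatial canvas for both the CNNs and the plate renderer.

## Normative model and deviation maps

The normative model is a per-location linear regression of sensitivity
on age with reference age 45 years — the simplest model consistent with
age-matched controls. It stores, per location: the mean at reference
age, the (non-positive) age slope, the residual spread, and empirical
percentile cutoffs at the 5 / 2 / 1 / 0.5% tails. Cutoffs are
location-specific empirical quantiles rather than Gaussian formulas,
matching how perimetric normative databases are built and staying
robust to skew. A residual-SD floor of 0.5 dB guards against degenerate
cohorts (the fit warns when it engages).

- **Total deviation (TD)** is the measured sensitivity minus the
  age-expected value.
- **General height (GH)** is the 7th-highest TD value of the 52
  (≈ the 85th percentile of the best locations), the conventional
  Humphrey estimator of overall field elevation or depression.
- **Pattern deviation (PD)** is TD − GH, which removes diffuse loss
  (typically media opacity such as cataract) and isolates localized
  loss.
- **Probability categories** follow the printed symbols: a deviation at
  or above the 5% cutoff is ">5%" (within normal limits); otherwise the
  most severe of {<5%, <2%, <1%, <0.5%} whose cutoff the value falls
  *strictly* below. The strict inequality matches the printed "<"
  labels, so a value exactly at a cutoff resolves to the less severe
  category. TD categories use the raw residual quantiles; PD categories
  use GH-corrected residual quantiles, i.e. the printout semantics of
  the PD probability plot.

## Global indices and reliability

**MD** is the variance-weighted mean of TD (weights 1/SD²), so
locations with tight normative spread count more. **PSD** is the
matching weighted dispersion of TD about MD with a finite-sample factor
N/(N−1). A verbal description of PSD as a sum of absolute differences
circulates in the clinical literature; it does not correspond to any
perimeter's actual index, so the package implements the standard
weighted-SD convention and documents the divergence here.

**VFI** is deliberately a simplified stand-in, labelled
`vfi_simplified` in all outputs, because the manufacturer's formula is
unpublished. Each location contributes a function score
`f = clamp(1 + dev/expected, 0, 1)`, where `dev` is the PD value in
mild-to-moderate loss (MD > −20 dB) and the TD value in advanced loss,
and a location within normal limits scores 1 outright so measurement
noise does not erode the index. Scores are averaged under centre
weights `exp(−(ecc/15)²)` reflecting the central field's dominant
functional contribution. The index is 100% for a perfect age-adjusted
field and 0% for a perimetrically blind one.

Records fail the **reliability filter** when fixation losses exceed
2/13 — interpreted strictly on the fraction, so other denominators are
admissible — or the false-positive rate exceeds 15%, or the
false-negative rate exceeds 25%. Boundary values pass, and every
excluded record carries the list of criteria that fired.

## The defect criterion

A glaucomatous field defect is called on the PD probability map when a
connected cluster of at least three contiguous *non-edge* points, all
at the <5% level or worse, contains at least one point at the <1% level
or worse ("or worse" qualifies by probability nesting). Edge points
neither join nor extend a cluster. Cluster search runs over the layout
adjacency; the reported qualifying cluster is the largest, with ties
broken by the more severe mean category, so reports are deterministic.

## The simulator

The simulator defines the study conditions for every experiment in the
test suite. Normal fields are the age-expected means plus a shared
subject-level height offset (SD 1 dB — the source of realistic GH
variation), independent per-location between-subject spread
(1.2 + 0.05·eccentricity dB, i.e. ~1.4 dB centrally to ~2.6 dB at the
rim), and measurement noise (default 1 dB). The generative means are
33.5 − 0.09·eccentricity dB at age 45 with a −0.06 dB/year slope —
values chosen once to resemble published white-on-white normative data.
Reliability indices are drawn so roughly 90% of records pass the
filter.

Defect archetypes are fixed location sets with full depth in the core
and half depth on the mask boundary: superior/inferior arcuate
(Bjerrum-band arc), nasal step (nasal points of one hemifield),
paracentral (cluster within ~9 degrees of fixation), advanced (union of
arcuate and nasal loss), plus the confounders — diffuse cataract-like
loss (uniform; depresses TD and MD but is absorbed by GH in PD),
hemianopia respecting the vertical midline (a neuro-ophthalmic
false-positive mode), and myopic rim loss confined to edge points.
Preperimetric records carry glaucoma labels but a defect depth capped
at 1 dB, below the categorization threshold: they are deliberately
irreducible error that stress-tests calibration, and they are retained
with a reliability-style flag rather than excluded so either protocol
can be replicated. The default class mix (35% normal, 48% glaucomatous
archetypes including 5% preperimetric, 17% confounders), severity range
4–16 dB and age range 25–80 years are the package's fixed simulation
conditions.

Cohorts are reproducible record by record: a global seed drives a
counter-derived substream per record, so parallel or partial
regeneration yields identical fields.

What the simulator does **not** emulate: staircase (SITA) threshold
noise structure, test–retest correlation beyond i.i.d. noise,
nerve-fibre-bundle trajectory geometry, or learning/fatigue artifacts.
Passing tests therefore demonstrate correctness of the pipeline under
controlled statistical structure, not clinical performance on real
fields.

## The map classifiers

No deep-learning framework is required: the package carries a compact
conv-net engine on base-R arrays (im2col convolution, batch
normalization, ReLU, identity residual blocks, dropout, global average
pooling, dense softmax head, Adam, backpropagation verified against
finite differences in the test suite). The map classifier is a small
residual CNN: a 3 × 3 stem, two residual blocks by default (1–8
configurable — a full-depth residual stack would over-parameterize a
72-cell input), dropout 0.25, and a 2-way softmax. The trunk keeps the
8 × 9 resolution throughout, so Grad-CAM needs no upsampling.

Inputs stack the map channel(s) with the occupancy mask: ND (raw dB),
NDP (PD values, dB), PDP (ordinal category codes 0–4 scaled to [0, 1];
a one-hot encoding was considered and rejected as unnecessary at this
input size). The dB channels are standardized with training-set
statistics and masked cells carry 0 *after* standardization, with the
mask as an explicit channel, so off-grid cells cannot imitate deep
defects. Training minimizes cross-entropy with Adam (lr 1e-3, weight
decay 1e-4, batch 64, up to 60 epochs, patience 10 — all configurable),
early-stops on validation AUC, and fixes the operating threshold by the
Youden index on validation scores only; test data never touch the
threshold. Records of one subject can never straddle the
training/validation split; an explicit split that tries raises an
error.

Ensemble fusion averages the available per-map softmax scores
(1–3 maps). A channel-stacked single-CNN variant (`map_kind =
"fusion"`) is provided as the alternative reading of a "fusion"
architecture; neither is claimed to be the original combination rule.

**Grad-CAM.** Channel weights are spatial means of the target-logit
gradient at the last residual stage; the weighted activation sum is
ReLU-rectified and max-normalized. One design choice deserves note: for
fields *without* a defect the raw class-evidence map is small in
magnitude, and max-normalizing it amplifies noise, so a share-of-total
concentration statistic is misleading there. The package therefore
exposes `normalize = FALSE`, and the test suite checks "no heated area
on preperimetric fields" as an absolute-magnitude statement (their
median raw heat mass is a small fraction of that of arcuate positives)
while checking localization on arcuate positives with the normalized
map (mean heat inside the defect mask exceeds the outside mean).

## The plate recognizer

The renderer draws printout-like PDP plates on a grayscale canvas
(defaults: 42 px cell pitch, 60 px grid margin, a frame rectangle inset
32 px, 3 px lines): frame, full-length cross axes through the field
origin, and one glyph per active location — a single 5 × 5 dot for
">5%", 2 × 2 / 3 × 3 / 4 × 4 dot stipples of increasing density for
"<5%", "<2%", "<1%", and a solid square (55% of the pitch) for
"<0.5%". Ink area increases strictly with severity. The margins are
generous so that every in-range capture warp keeps the whole frame
inside the canvas.

Capture simulation composes a projective warp (rotation ≤ 3 degrees
about the canvas centre plus independent corner jitter ≤ 3% of the
width), Gaussian blur (σ ≤ 1.2 px), brightness/contrast jitter (≤ 15%)
and additive noise (SD ≤ 3 gray levels). Magnitudes are drawn uniformly
within the ranges; the ground-truth homography and cross position are
composed with the applied warp, and zero magnitudes reproduce the plate
bit for bit.

Localization binarizes at the intensity midrange, estimates the four
frame corners from the extreme ink pixels (averaged over a small
corner neighbourhood for sub-pixel stability), solves the
canonical-to-image homography from the four correspondences, and
verifies ink along both cross axes (probing a ±3 px perpendicular
window, since a 3 px line blurred at σ = 1.2 sits near the threshold).
A blank or cross-less image raises a structured `vf_detection_error`,
the signal for an unusable capture. On clean plates the recovered
centre is sub-pixel; across in-range captures the observed worst-case
error is well under a quarter of the cell pitch. Cells are then
enumerated at fixed pitch from the known plate geometry — the
standardized-printout assumption — and each 1.2-pitch patch (1.0 cell
plus 20% margin) is rectified to 32 × 32 through the estimated
homography.

The six-class glyph classifier (blank + five symbols) is three
conv–batch-norm–ReLU stages (strides 2, 2, 1), global average pooling
and a 6-way softmax under cross-entropy. It trains on patches extracted
through the *estimated* homography of capture-augmented rendered
plates, so training sees the same localization jitter as deployment.
Image diagnosis chains localization, recognition, reconstruction of the
category map (an active cell recognized as blank counts as ">5%"), the
PDP map classifier at its fixed operating threshold, and the Grad-CAM
overlay; failures propagate with stage attribution and no score is
emitted.

## Diagnostic statistics

AUC uses the rank statistic with tie correction; confidence intervals
and AUC comparisons use DeLong's method (the package guards the
degenerate self-comparison, returning z = 0, p = 1). The Youden
threshold sweeps midpoints between adjacent distinct scores and breaks
ties toward higher specificity; a positive call is score ≥ threshold.
Sensitivity/specificity intervals are Wilson score intervals (the CI
method was unstated upstream; Wilson behaves well at the small strata
sizes subgroup analysis produces). Weighted kappa defaults to linear
disagreement weights with quadratic selectable — both conventions are
common and the upstream choice is unknown. Group comparisons are the
two-sided Wilcoxon rank-sum (normal approximation with continuity
correction under ties) and the classical Pearson chi-square without
continuity correction. Subgroup evaluation stratifies by eye, age
(<60 vs ≥60 years; exactly 60 falls in the older stratum) and severity
(MD > −6 dB vs ≤ −6 dB; exactly −6 falls in the more severe stratum),
always at the fixed threshold; single-class strata are flagged rather
than failed.

## Problem sizes and numerical choices

The test suite and the acceptance script run at fixed desk-scale sizes
chosen as the package's own study conditions: normative fits on
cohorts of 150–2,000 simulated records; classifier recovery on a
separable cohort of 2,000 fields with a 400-field validation split;
statistical calibration on 52,000 location-observations; the
recognition experiment on 200 captured plates (14,400 cells) with the
glyph classifier trained on 60 plates for 12 epochs. Determinism is
end-to-end: every stochastic stage consumes an explicit seed, and
training twice with identical data and seed reproduces the same
parameters and threshold.

Other numerical conventions: empirical cutoff ties are nudged to keep
the 5 > 2 > 1 > 0.5% ordering strict; batch normalization uses batch
statistics in training and running statistics at inference (the
backward pass respects the mode); minibatches of size 1 are skipped
(batch statistics would be undefined); Adam uses decoupled weight decay
on convolution and dense weights only.

## Known limitations

Real VF printouts vary in fonts, scan resolution and artifacts the
renderer does not model; the recognizer is trained on its own glyphs
and makes no claim about third-party printouts. The simplified VFI is
not the proprietary index. The simulator's i.i.d. noise understates
test–retest correlation, so classifier AUCs on simulated cohorts
overstate what the same architecture would achieve on clinical data.
Octopus and other non-Humphrey formats, 10-2/30-2 patterns, kinetic
perimetry, OCR of report text and longitudinal progression indices are
out of scope.
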