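# vfscreen

Tools for Humphrey 24-2 visual-field (VF) analysis and deep-learning
glaucoma screening, for researchers who need a complete, reproducible
desk-scale pipeline: the 24-2 test-point geometry, normative deviation
maps, global indices, the clinical defect criterion, a labelled VF
simulator, compact CNN classifiers with Grad-CAM, a printed
pattern-deviation-plate recognizer, and ROC/agreement statistics.

## What it computes

For a field of measured sensitivities `s_i` (dB) at the 52 active 24-2
locations and a normative model with age-expected values `n_i(age)`,
per-location spread `SD_i` and empirical tail cutoffs:

- **Total deviation** `TD_i = s_i − n_i(age)`; **general height**
  `GH = TD_(7)` (the 7th-highest TD); **pattern deviation**
  `PD_i = TD_i − GH`.
- **Probability categories** per location: `>5%`, `<5%`, `<2%`, `<1%`,
  `<0.5%` by strict comparison against the 5/2/1/0.5% empirical
  cutoffs — the symbols of the printed probability plots.
- **MD** `= Σ w_i TD_i / Σ w_i` and
  **PSD** `= sqrt(N/(N−1) · Σ w_i (TD_i − MD)² / Σ w_i)` with
  `w_i = 1/SD_i²`; a simplified **VFI** (labelled `vfi_simplified`).
- **Glaucomatous defect rule** on the PD probability map: a cluster of
  ≥ 3 contiguous non-edge points at `<5%` or worse containing ≥ 1 point
  at `<1%` or worse.
- **Screening CNNs**: small residual networks over the 8 × 9 grid
  embedding of the ND / NDP (PD) / PDP maps, ensemble fusion by score
  averaging, Youden operating thresholds fixed on validation data, and
  Grad-CAM heatmaps.
- **Plate recognition**: rendering of printout-like PDP plates, a
  smartphone-capture simulator (perspective, rotation, blur,
  photometric jitter, noise), frame/cross localization by homography,
  and a six-class glyph CNN that reconstructs the category map from the
  image, feeding the same screening classifier.
- **Evaluation**: AUC with DeLong CIs and comparisons, Youden
  thresholds, sensitivity/specificity with Wilson CIs, weighted kappa,
  Wilcoxon/chi-square, and subgroup analysis by eye, age and severity.

The methods vignette (`vignettes/vfscreen-methods.Rmd`) documents every
model, convention and design decision.

## Worked example

```r
library(vfscreen)
layout <- vf_layout("right")          # 54 nominal, 52 active locations

# normative model fitted on 300 simulated non-glaucoma fields
set.seed(2024)
controls <- lapply(1:300, function(i)
  sample_normal_field(runif(1, 25, 80), normative_truth(layout), id = i))
norm <- fit_normative(controls)

# a field with a deep superior arcuate defect
set.seed(7)
rec <- apply_archetype(sample_normal_field(58, normative_truth(layout)),
                       "arcuate_sup", severity = 12)
gi <- global_indices(rec, norm, layout)
round(c(md = gi$md, psd = gi$psd, vfi = gi$vfi_simplified, gh = gi$gh), 2)
#>   md  psd  vfi   gh
#> 0.56 3.10 95.20 3.66
glaucomatous_defect(gi$maps$pd_cat, layout)
#> Glaucomatous defect: PRESENT (2 abnormal cluster(s))
```

This subject's field is globally elevated (GH ≈ +3.7 dB), which almost
cancels the localized arcuate loss in MD (≈ +0.6 dB) — exactly the
situation where a mean index misleads. The elevated PSD (≈ 3.1 dB)
flags the irregularity, and after the general-height correction the
defect stands out on the pattern-deviation probability map, where the
cluster rule finds a qualifying cluster of depressed non-edge points.

End-to-end image screening:

```r
glyph <- train_glyph_model(n_plates = 60, seed = 424)    # six-class symbol CNN
cnn   <- train_vf_model(build_vf_model("PDP", seed = 3),
                        simulate_cohort(sim_config(2000, seed = 77))$records,
                        norm = norm, seed = 3)
plate <- augment_capture(render_plate(gi$maps$pd_cat, layout))
diagnose_from_image(plate$pixels, glyph, cnn)$label
#> [1] "glaucoma"
```

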