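---
title: "Methods: stenosis triage by deep analysis of the LV myocardium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stenosis triage by deep analysis of the LV myocardium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Coronary CT angiography grades the worst stenosis of each coronary artery
into ordinal categories (0%, 1–24%, 25–49%, 50–69%, ≥ 70%, or
non-diagnostic). Grading is sensitive but poorly specific for *functional*
significance — whether the lesion actually limits flow, the property that
justifies revascularization. The invasive reference is fractional flow
reserve: a patient is labelled positive when any vessel has FFR ≤ 0.80
(inclusive), or, where FFR is not wired because the stenosis is angiographic
high-grade (≥ 90% diameter stenosis), by that finding alone.

`lvmtriage` implements a combined decision scheme built on one clinical
observation: grading is already reliable at the extremes. Patients whose
maximum grade is ≤ 24% are called negative (probability 0), ≥ 70% positive
(probability 1), and only the intermediate band (25–69%) is deferred to a
learned classifier of the left ventricular myocardium, on the hypothesis
that a flow-limiting stenosis leaves subtle traces (texture,
hypo-attenuation, shape) in the resting myocardium itself.

The learned part has three stages:

1. **Voxelwise LVM segmentation.** Each voxel is classified from six 2D
   patches — axial, coronal, sagittal planes through the voxel, at a fine
   (1×) and a coarse (3×, linearly interpolated) in-plane sampling — by a
   two-stream network: per stream two 3×3-convolution + 2×2-max-pool blocks,
   streams concatenated into a fused fully connected layer and a logistic
   output. Out-of-grid samples are mirror-reflected. Training draws equal
   numbers of myocardium and background voxels per volume because masks are
   a small voxel minority.
2. **Unsupervised characterization.** A convolutional auto-encoder is
   trained on axial patches (default 16×16) centred on myocardial voxels:
   two conv + max-pool blocks into a dense bottleneck (default 16
   dimensions); the decoder is a single fully connected expansion back to
   the patch, a deliberately lean choice that trains robustly at this patch
   size while keeping the encoder — the part whose output is used — fully
   convolutional. The bottleneck vector is the voxel's *encoding*.
3. **Patient features and classification.** Per encoding dimension, seven
   statistics (mean, SD, min, quartiles, max; percentiles by linear
   interpolation between order statistics) over all LVM voxels give a
   fixed-length patient vector (default 16 × 7 = 112). An RBF-kernel SVM
   with inverse-prevalence class weights maps it to a Platt-calibrated
   probability. Features are standardized with training-fold statistics
   only, and the regularization constant is chosen by an inner stratified
   grid search on the training folds only — both leakage guards.

Evaluation mirrors the intended clinical protocol: repeated stratified
k-fold cross-validation over the *intermediate* patients (each gets exactly
one out-of-fold probability per repetition), extremes injected with their
rule-based 0/1 probabilities, tie-aware empirical ROC/AUC over all
patients, and mean ± SD across repetitions. Proportion metrics carry exact
Clopper–Pearson 95% intervals; zero-denominator metrics are reported absent
rather than zero.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `patch_edge`, `scales` | 25, {1, 3} (fixtures use 11) | voxels / factor | odd edge centres the voxel; coarse scale adds context |
| segmenter epochs / samples | 10 / 1000 per volume | — | below this the loss has not converged on phantoms and held-out Dice suffers |
| `encoding_dim` | 16 | — | strict compression of 256-pixel patches; features stay small |
| CAE patch size | 16 × 16 | voxels | covers the phantom wall thickness with context |
| statistic set | mean, sd, min, p25, p50, p75, max | — | robust location/scale/extremes per dimension |
| SVM cost grid | {0.1, 1, 10} | — | nested selection; single value skips the search |
| CV plan | k = 10, 50 repetitions | — | fold randomization redrawn each repetition |
| triage threshold | 0.5 | probability | operating point for binary metrics, configurable |
| QC volume range / CC fraction | 1–500 mL / 0.8 | — | catches empty, runaway and fragmented masks |

All randomness flows from one integer seed through deterministic
per-purpose derived streams, so cohorts, trained networks, fold splits and
reports are bit-identically reproducible and independent of generation
order.

## The synthetic cohort generator

Real CCTA with invasive reference data cannot ship with a package, so the
generator emulates the statistical skeleton the pipeline relies on:

* an ellipsoidal myocardial shell (randomized centre, semi-axes, wall
  thickness 2.5–3.5 mm) around a contrast-bright blood pool (+400 HU)
  against soft-tissue background (−50 HU), myocardium at +100 HU, Gaussian
  noise (default SD 15 HU) — typical contrast-enhanced CCTA ranges;
* in positive patients, a contiguous angular sector of the shell (default a
  quarter of the circumference) depressed by `effect_size` HU with
  cosine-tapered edges — mimicking subendocardial hypo-attenuation without
  claiming anatomical realism. `effect_size` is the single signal dial: 0
  makes positives radiologically identical to negatives;
* cohort structure matching the study design: 126 patients split 2/8/10/91/15
  across the five grades, 81 positives allocated with none below 25% DS,
  one to three vessels per patient (the maximum grade defines the
  category), occasional non-diagnostic vessels, 23 prior-event patients;
* invasive physiology consistent with the reference rule: 85% of positives
  via minimum FFR drawn on [0.55, 0.80], 15% via an ICA high-grade lesion
  (FFR not wired in that vessel); negatives on [0.82, 0.95] with ICA < 90 —
  brackets the observed clinical spread without modelling hemodynamics.

What the phantoms deliberately do **not** contain: real anatomy (papillary
muscles, trabeculation, neighbouring chambers), beam-hardening and motion
artifacts, scanner/protocol variation, and any genuine link between
coronary anatomy and myocardial appearance. Passing tests on phantoms
therefore demonstrates that the pipeline's machinery is correct and can
recover a known planted signal — not that the clinical effect size is
recoverable from real resting CCTA.

## Numerical and design choices

* **Indexing convention:** arrays are `(z, y, x)`, 1-based, axial = fixed
  `z`; one stated convention beats silent mixes. Volumes are stored as
  int16 HU NIfTI, masks as uint8.
* **Padding:** mirror reflection for every patch sampler (segmentation and
  CAE alike), avoiding HU cliffs at grid borders.
* **Networks:** implemented in-package as im2col convolutions, 2×2 max
  pooling (deterministic first-index tie-break), dense layers and Adam
  (lr 1e-3). Intensities are scaled by 1/200 before entering a network.
  Max pooling truncates odd trailing rows; the minimum patch edge for the
  two-block encoder is 11 (segmentation) / 9 (CAE).
* **Calibration:** Platt sigmoid fitted by BFGS on training decision values
  with the standard smoothed targets; the sign of the slope is learned, so
  the orientation of the SVM decision axis never matters downstream.
  Fitting on resubstitution decision values makes the sigmoid steeper than
  a held-out fit would; ranks — hence AUC — are unaffected.
* **CAE training scope:** the auto-encoder is trained once, without labels,
  on patches pooled across the whole cohort; only the SVM is refit inside
  every cross-validation fold. The encoder never sees labels, so the
  leakage-sensitive stage is the supervised one, and this keeps repeated
  CV tractable.
* **Per-voxel encodings** (rather than per-slice aggregates) are the
  implemented interpretation; features are invariant to voxel order by
  construction.
* **Ordinal DS scores:** grades stay categorical; the DS-only ROC uses
  their ranks 0–4. The packaged grade-by-outcome table — per grade
  (positives, negatives) = (0,2), (0,8), (6,4), (61,30), (14,1) — yields
  ordinal AUC 0.676 and every diagnostic percentage quoted in the README.
* **Non-diagnostic grades:** ignored whenever any diagnostic grade exists;
  all-ND patients have no triage group and are excluded explicitly, the
  same path as image-quality exclusions.
* **Degenerate inputs** are rejected loudly: empty masks (encoding), empty
  encoding sets (features), single-class training sets (SVM), missing
  classifier probabilities for intermediates, classifier probabilities
  supplied for extremes, stratification with a class smaller than k.

## Problem sizes used by the tests and acceptance script

Phantoms are 32³ voxels at 1 mm isotropic spacing; segmenters train on 4
volumes (patch edge 11) and are scored on held-out phantoms at stride 1;
the auto-encoder trains on a few hundred to 2000 patches for 5–10 epochs;
classifier studies use 60-patient cohorts (5-fold CV, 3 repetitions) and
the combined-triage study a full 126-patient cohort (10-fold CV, 10
repetitions). These sizes were chosen so each experiment carries a clear
signal while any workstation reproduces the whole suite comfortably.

## Known limitations

* The combined-vs-grade-only comparison at `effect_size = 0` is an honest
  null experiment, and its statistic — pooled repeated-CV AUC over 101
  intermediates — has an irreducible sampling SD of roughly 0.05–0.06
  across cohort draws: a single synthetic cohort can land a few hundredths
  above or below the grade-only AUC without any defect in the pipeline.
  Interpret single-cohort null differences smaller than ~0.1 as noise;
  averaging over cohorts is the reliable null check.
* Phantom realism is intentionally minimal (see above); absolute Dice and
  AUC values on phantoms say nothing quantitative about clinical data.
* Results are patient-level only: the method does not localize which vessel
  or lesion is functionally significant.
* The tiny networks are sized for CPU-scale fixtures; scaling to full-size
  clinical volumes would warrant a compiled backend and larger
  architectures, without changes to any interface.
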