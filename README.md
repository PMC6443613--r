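# lvmtriage

Identification of patients with a **functionally significant coronary artery
stenosis** from resting coronary CT angiography (CCTA), for imaging
scientists and method developers working on CT-based ischemia triage.

Visual grading of the degree of stenosis (DS) on CCTA is sensitive but
unspecific: many anatomically intermediate lesions (25–69% DS) do not limit
flow. `lvmtriage` implements a combined decision scheme that keeps the
cheap, reliable part of DS grading and defers only the ambiguous middle to
an image-based learned classifier of the **left ventricular myocardium
(LVM)**:

1. **Segmentation** — a two-stream multiscale convolutional network
   classifies single voxels as myocardium or background from six triplanar
   patches (axial/coronal/sagittal, fine and coarse scale) centred on the
   voxel, followed by automated segmentation quality control.
2. **Characterization** — a convolutional auto-encoder (CAE), trained
   without labels, compresses the axial patch around every myocardial voxel
   into a low-dimensional encoding.
3. **Patient features** — statistics (mean, SD, min, quartiles, max) of the
   encodings over all LVM voxels form one fixed-length feature vector per
   patient.
4. **Classification** — an RBF support vector machine with training-fold
   standardization and Platt-calibrated probabilities.
5. **Triage rule** — patients with maximum DS ≤ 24% get probability 0,
   ≥ 70% get probability 1, and intermediates (25–69%) get the classifier's
   probability:

   `p(patient) = 0` if DS ≤ 24%, `1` if DS ≥ 70%, `p_SVM(features)` otherwise.

The reference standard is the invasive one: a patient is positive when any
vessel has fractional flow reserve **FFR ≤ 0.80** (boundary inclusive) or a
high-grade (**≥ 90%** DS) stenosis on invasive angiography.

The package also contains the full evaluation harness — repeated stratified
k-fold cross-validation (default 50 × 10-fold), sensitivity / specificity /
PPV / NPV / accuracy with exact (Clopper–Pearson) confidence intervals, and
a tie-aware empirical ROC with AUC = (concordant + ½·tied) / (n⁺·n⁻) — plus
a synthetic phantom cohort generator (ellipsoidal myocardial shells with
hypo-attenuating lesion sectors in contrast-enhanced chest-like volumes) so
every stage is testable without clinical data.

## Worked example

```r
library(lvmtriage)

# a 20-patient synthetic cohort with strong myocardial lesions
config <- pipeline_config(
  out_dir = "demo_out", seed = 1,
  synth = cohort_spec(n_patients = 20, prevalence = 0.5,
                      category_counts = c(0L, 2L, 4L, 11L, 3L),
                      effect_size = 60, seed = 1),
  segmentation = list(n_train = 4),
  cv = list(k = 3, repetitions = 5))
report <- run_pipeline(config)
```

The run logs each stage and ends with lines like

```
[qc] 20 of 20 patients pass segmentation QC
[evaluate] DS-only AUC 0.715; running 5x3-fold CV
[report] combined AUC 0.780 +/- 0.034 (DS-only 0.715)
```

meaning: all automatic segmentations passed quality control; grading alone
discriminates positives from negatives with AUC 0.72 on this cohort; adding
the learned myocardial analysis for the ~15 intermediate patients raises
the AUC to 0.78 (mean ± SD over the 5 cross-validation repetitions — at
this tiny cohort size each fold trains on ten patients, so the gain is
modest; the acceptance script's 126-patient run shows the full effect).
`demo_out/` then contains
`cohort.csv`, `features.csv`, `predictions.csv`, `roc_ds.tsv`,
`roc_combined.tsv` and `report.json` (seed and config hash embedded; a
rerun with the same configuration is bit-identical).

The packaged grade-by-outcome contingency table reproduces the headline
diagnostic numbers of DS-only grading directly:

```r
tab <- build_ordinal_fixture()
diagnostic_metrics(contingency_counts(tab, "G3"))  # threshold >= 50% DS
#>   sensitivity   92.6% (75/81) [84.6-97.2]
#>   specificity   31.1% (14/45) [18.2-46.6]
#>   ...
sc <- contingency_to_scores(tab)
roc_auc(sc$scores, sc$labels)$auc                  # 0.676
```

A thin command-line wrapper with `synth`, `run` and `table` subcommands is
installed under `inst/cli/lvmtriage.R`.

### File formats

Volumes: NIfTI (`.nii.gz`), int16 HU; masks: uint8 {0,1} NIfTI on the same
grid. Cohort tables: CSV, one row per vessel with columns `patient_id`,
`vessel_id`, `ccta_grade` (`G0`=0%, `G1`=1–24%, `G2`=25–49%, `G3`=50–69%,
`G4`=≥70%, `ND`=non-diagnostic), `ffr` (empty = not measured),
`ica_ds_percent`, `prior_event`, `true_label`. Packaged examples live in
`inst/extdata/` (`example_cohort.csv`, `ds_contingency.csv`).

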