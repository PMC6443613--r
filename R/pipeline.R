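# End-to-end pipeline: synthetic cohort (optional) -> segmentation -> QC ->
# encoding -> features -> repeated CV with the triage rule -> report files.

#' Pipeline configuration
#'
#' Assembles the per-stage settings of [run_pipeline()] into one list. Every
#' random draw anywhere in the pipeline derives from `seed`, so a rerun with
#' an identical configuration is bit-identical.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global integer seed.
#' @param synth `NULL`, or a [cohort_spec()] (or list of its arguments) to
#'   generate a synthetic cohort.
#' @param cohort_csv,volume_dir existing cohort table and NIfTI volume
#'   directory (`<patient_id>.nii.gz`, optional `<patient_id>_mask.nii.gz`),
#'   used when `synth` is `NULL`.
#' @param use_true_masks skip the segmentation network and use the provided
#'   masks directly (for ablations and fast runs).
#' @param segmentation,autoencoder,features,cv,qc per-stage settings; see
#'   [train_segmenter()], [train_autoencoder()], [summarize_encodings()],
#'   [cv_plan()] and [qc_segmentation()]. `segmentation$n_train` volumes
#'   (with masks) are used to fit the segmenter; `segmentation$stride` and
#'   `autoencoder$stride` control voxel subsampling.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, synth = NULL,
                            cohort_csv = NULL, volume_dir = NULL,
                            use_true_masks = FALSE,
                            segmentation = list(), autoencoder = list(),
                            features = list(), cv = list(), qc = list()) {
  seg <- utils::modifyList(list(n_train = 4L, stride = 2L, patch_edge = 11L,
                                scales = c(1, 3), epochs = 10L, seed_offset = 11L),
                           segmentation)
  cae <- utils::modifyList(list(encoding_dim = 16L, patch_size = 16L,
                                stride = 2L, epochs = 5L, n_patches = 2000L,
                                seed_offset = 23L),
                           autoencoder)
  fea <- utils::modifyList(list(statistics = c("mean", "sd", "min", "p25",
                                               "p50", "p75", "max")),
                           features)
  cvp <- utils::modifyList(list(k = 10L, repetitions = 10L, threshold = 0.5,
                                cost_grid = 1), cv)
  qcc <- utils::modifyList(list(min_volume_ml = 1, max_volume_ml = 500,
                                min_cc_fraction = 0.8), qc)
  if (!is.null(synth) && !inherits(synth, "cohort_spec"))
    synth <- do.call(cohort_spec, synth)
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 cohort_csv = cohort_csv, volume_dir = volume_dir,
                 use_true_masks = isTRUE(use_true_masks),
                 segmentation = seg, autoencoder = cae, features = fea,
                 cv = cvp, qc = qcc),
            class = "pipeline_config")
}

#' Auto-encoder features for a whole cohort
#'
#' Trains the convolutional auto-encoder on patches sampled from the masked
#' myocardium of every patient (unless a trained `cae` is supplied), encodes
#' each patient's myocardial voxels, and summarizes the encodings into one
#' feature vector per patient.
#'
#' @param volumes,masks named lists (by patient id) of volumes and binary
#'   myocardium masks.
#' @param cae optional pre-trained [train_autoencoder()] model.
#' @param encoding_dim,patch_size,epochs auto-encoder settings.
#' @param stride voxel stride for encoding extraction.
#' @param n_patches total training patches sampled across the cohort.
#' @param statistics statistic set for [summarize_encodings()].
#' @param seed integer seed (patch sampling and training).
#' @return list with `features` (data frame, one row per patient), `cae`
#'   (the trained model).
#' @export
cohort_features <- function(volumes, masks, cae = NULL, encoding_dim = 16L,
                            patch_size = 16L, epochs = 10L, stride = 2L,
                            n_patches = 2000L,
                            statistics = c("mean", "sd", "min", "p25", "p50",
                                           "p75", "max"),
                            seed = 1L) {
  ids <- names(volumes)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(masks))))
  if (is.null(cae)) {
    train_patches <- with_seed(derive_seed(seed, 1L), {
      per_pat <- max(1L, n_patches %/% max(1L, length(ids)))
      lst <- lapply(ids, function(pid) {
        vol <- if (inherits(volumes[[pid]], "ct_volume")) volumes[[pid]]$data else volumes[[pid]]
        idx <- which(masks[[pid]] != 0)
        if (length(idx) == 0) return(NULL)
        sel <- idx[sample.int(length(idx), min(per_pat, length(idx)))]
        extract_axial_patches(vol, arrayInd(sel, dim(masks[[pid]])), patch_size)
      })
      lst <- Filter(Negate(is.null), lst)
      tot <- sum(vapply(lst, function(a) dim(a)[4], numeric(1)))
      out <- array(0, c(patch_size, patch_size, 1L, tot))
      at <- 0L
      for (a in lst) {
        out[, , , at + seq_len(dim(a)[4])] <- a
        at <- at + dim(a)[4]
      }
      out
    })
    cae <- train_autoencoder(train_patches, encoding_dim,
                             list(epochs = epochs, seed = derive_seed(seed, 2L)))
  }
  feats <- lapply(ids, function(pid) {
    enc <- encode_lvm(cae, volumes[[pid]], masks[[pid]], stride = stride,
                      patient_id = pid)
    summarize_encodings(enc, statistics)
  })
  names(feats) <- ids
  list(features = feature_table(feats), cae = cae)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  plain$out_dir <- NULL  # the analytic identity of a run excludes where it lands
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full triage pipeline
#'
#' Executes, in order: cohort synthesis (or loading), segmentation-network
#' training and inference (unless `use_true_masks`), segmentation QC with
#' exclusion accounting, auto-encoder training and per-voxel encoding,
#' patient feature extraction, repeated stratified cross-validation of the
#' SVM with the triage rule, and report writing. Outputs in `out_dir`:
#' `cohort.csv` (when synthesized), `features.csv`, `predictions.csv`
#' (mean combined probability per patient), `roc_ds.tsv`,
#' `roc_combined.tsv`, and `report.json` (seed, config hash, exclusions,
#' DS-only and combined performance). Reruns with the same configuration
#' are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # ---- cohort ----
  if (!is.null(config$synth)) {
    pipeline_log("synth", "generating synthetic cohort (n=%d, seed %d)",
                 config$synth$n_patients, config$synth$seed)
    cohort <- generate_cohort(config$synth)
    records <- cohort$records
    volumes <- cohort$volumes
    true_masks <- cohort$masks
    spacing <- config$synth$voxel_spacing
    write_cohort_table(cohort$table, file.path(config$out_dir, "cohort.csv"))
  } else {
    if (is.null(config$cohort_csv) || is.null(config$volume_dir))
      stop("either `synth` or both `cohort_csv` and `volume_dir` must be given")
    records <- read_cohort_table(config$cohort_csv)
    volumes <- list(); true_masks <- list()
    for (r in records) {
      path <- file.path(config$volume_dir, paste0(r$patient_id, ".nii.gz"))
      if (!file.exists(path))
        stop("missing volume file for patient ", r$patient_id, ": ", path)
      volumes[[r$patient_id]] <- read_volume(path)
      mpath <- file.path(config$volume_dir, paste0(r$patient_id, "_mask.nii.gz"))
      if (file.exists(mpath)) true_masks[[r$patient_id]] <- read_mask(mpath)
    }
    spacing <- volumes[[1]]$spacing
  }
  ids <- vapply(records, `[[`, character(1), "patient_id")
  n <- length(records)

  # ---- segmentation ----
  segc <- config$segmentation
  if (config$use_true_masks) {
    pipeline_log("segment", "using provided masks for %d patients", n)
    masks <- true_masks
  } else {
    n_train <- min(segc$n_train, n)
    train_ids <- ids[seq_len(n_train)]
    if (!all(train_ids %in% names(true_masks)))
      stop("segmentation training requires masks for patients: ",
           paste(setdiff(train_ids, names(true_masks)), collapse = ", "))
    pipeline_log("segment", "training segmenter on %d volumes", n_train)
    pspec <- patch_spec(segc$patch_edge, segc$scales)
    model <- train_segmenter(volumes[train_ids], true_masks[train_ids], pspec,
                             list(epochs = segc$epochs,
                                  seed = derive_seed(seed, segc$seed_offset)))
    masks <- lapply(ids, function(pid) {
      segment_volume(model, volumes[[pid]], stride = segc$stride)
    })
    names(masks) <- ids
  }

  # ---- QC ----
  qcres <- lapply(ids, function(pid)
    do.call(qc_segmentation, c(list(mask = masks[[pid]], spacing = spacing),
                               config$qc)))
  names(qcres) <- ids
  excluded <- ids[!vapply(qcres, `[[`, logical(1), "pass")]
  keep <- setdiff(ids, excluded)
  for (pid in excluded)
    pipeline_log("qc", "excluding %s: %s", pid,
                 paste(qcres[[pid]]$reasons, collapse = "; "))
  pipeline_log("qc", "%d of %d patients pass segmentation QC",
               length(keep), n)
  records <- records[ids %in% keep]
  ids <- keep
  n <- length(ids)

  # ---- triage grouping ----
  groups <- vapply(records, function(r)
    triage_group(patient_max_grade(r$vessel_grades), nd_action = "exclude"),
    character(1))
  nd_excluded <- ids[is.na(groups)]
  if (length(nd_excluded)) {
    pipeline_log("triage", "excluding all-ND patients: %s",
                 paste(nd_excluded, collapse = ", "))
    records <- records[!is.na(groups)]
    ids <- ids[!is.na(groups)]
    groups <- groups[!is.na(groups)]
    n <- length(ids)
  }
  labels <- vapply(records, reference_label, logical(1))

  # ---- auto-encoder + features ----
  caec <- config$autoencoder
  inter_ids <- ids[groups == "intermediate"]
  pipeline_log("encode", "training auto-encoder and summarizing %d patients", n)
  cf <- cohort_features(volumes[ids], masks[ids],
                        encoding_dim = caec$encoding_dim,
                        patch_size = caec$patch_size, epochs = caec$epochs,
                        stride = caec$stride, n_patches = caec$n_patches,
                        statistics = config$features$statistics,
                        seed = derive_seed(seed, caec$seed_offset))
  ftab <- cf$features
  utils::write.csv(ftab, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)

  # ---- evaluation ----
  cvc <- config$cv
  ds_scores <- vapply(records, function(r)
    grade_rank(patient_max_grade(r$vessel_grades)) - 1, numeric(1))
  ds_roc <- roc_auc(ds_scores, labels)
  write_roc_tsv(ds_roc, file.path(config$out_dir, "roc_ds.tsv"))
  pipeline_log("evaluate", "DS-only AUC %.3f; running %dx%d-fold CV",
               ds_roc$auc, cvc$repetitions, cvc$k)
  plan <- cv_plan(k = cvc$k, repetitions = cvc$repetitions,
                  seed = derive_seed(seed, 31L))
  cvres <- run_repeated_cv(ftab, labels, groups, plan,
                           svm_config = list(cost_grid = cvc$cost_grid),
                           threshold = cvc$threshold)
  mean_prob <- rowMeans(cvres$probabilities)
  utils::write.csv(data.frame(patient_id = ids, group = groups,
                              probability = round(mean_prob, 6),
                              label = labels),
                   file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  comb_roc <- roc_auc(mean_prob, labels)
  write_roc_tsv(comb_roc, file.path(config$out_dir, "roc_combined.tsv"))

  report <- list(
    seed = seed,
    config_hash = config_hash(config),
    n_input = length(qcres),
    n_excluded_qc = length(excluded),
    excluded_qc = as.list(excluded),
    n_excluded_nd = length(nd_excluded),
    n_evaluated = n,
    n_intermediate = length(inter_ids),
    prevalence = mean(labels),
    ds_only = list(auc = ds_roc$auc),
    combined = lapply(cvres$aggregate, function(a)
      list(mean = unname(a["mean"]), sd = unname(a["sd"]))),
    per_repetition = as.list(cvres$per_repetition)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  pipeline_log("report", "combined AUC %.3f +/- %.3f (DS-only %.3f)",
               cvres$aggregate$auc["mean"], cvres$aggregate$auc["sd"],
               ds_roc$auc)
  invisible(report)
}
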