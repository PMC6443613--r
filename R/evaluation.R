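# Evaluation harness: reference-standard labelling, confusion metrics with
# exact binomial confidence intervals, tie-aware empirical ROC/AUC,
# repeated stratified cross-validation, and the packaged reconstruction of
# the grade-by-outcome contingency table.

#' Reference-standard label for functionally significant stenosis
#'
#' A patient is positive when any vessel has an invasive FFR at or below
#' 0.80 (the boundary is inclusive) or any vessel shows a high-grade
#' stenosis of at least 90 percent on invasive angiography. At least one
#' physiology value must be present.
#'
#' @param record a patient record with `ffr_values` and `ica_ds_percent`
#'   (either may contain `NA` = not measured), or a list with those fields.
#' @return logical.
#' @export
reference_label <- function(record) {
  ffr <- record$ffr_values
  ica <- record$ica_ds_percent
  ffr <- ffr[!is.na(ffr)]
  ica <- ica[!is.na(ica)]
  if (length(ffr) == 0 && length(ica) == 0)
    stop("no invasive physiology (FFR or ICA DS) available for patient ",
         record$patient_id %||% "?")
  any(ffr <= 0.80) || any(ica >= 90)
}

#' Confusion counts of binary predictions
#'
#' @param predicted,labels logical vectors of equal length.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(predicted, labels) {
  predicted <- as.logical(predicted)
  labels <- as.logical(labels)
  if (length(predicted) != length(labels))
    stop("`predicted` and `labels` differ in length")
  structure(list(tp = sum(predicted & labels),
                 fp = sum(predicted & !labels),
                 tn = sum(!predicted & !labels),
                 fn = sum(!predicted & labels)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

binom_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(k, n, conf.level = conf)$conf.int)
}

metric_entry <- function(k, n) {
  if (n == 0)
    return(list(estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                num = k, den = n))
  ci <- binom_ci(k, n)
  list(estimate = k / n, lower = ci[1], upper = ci[2], num = k, den = n)
}

#' Diagnostic metrics with exact binomial confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy from confusion counts, each with an exact (Clopper-Pearson)
#' 95 percent confidence interval. A metric whose denominator is zero is
#' reported as absent (`NA`), never as 0.
#'
#' @param counts a [confusion_counts()].
#' @return list of class `diagnostic_metrics`; each element has `estimate`,
#'   `lower`, `upper`, `num`, `den` (fractions in `[0, 1]`).
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, structure(list(
    sensitivity = metric_entry(tp, tp + fn),
    specificity = metric_entry(tn, tn + fp),
    ppv = metric_entry(tp, tp + fp),
    npv = metric_entry(tn, tn + fn),
    accuracy = metric_entry(tp + tn, tp + fp + tn + fn)
  ), class = "diagnostic_metrics", counts = counts))
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  for (nm in names(x)) {
    e <- x[[nm]]
    if (is.na(e$estimate)) {
      cat(sprintf("  %-12s absent (0 denominator)\n", nm))
    } else {
      cat(sprintf("  %-12s %5.1f%% (%d/%d) [%.1f-%.1f]\n", nm,
                  100 * e$estimate, e$num, e$den,
                  100 * e$lower, 100 * e$upper))
    }
  }
  invisible(x)
}

#' Tie-aware empirical ROC curve and AUC
#'
#' The AUC is the pairwise concordance `(concordant + 0.5 * tied) /
#' (n_pos * n_neg)`, computed through the rank (Mann-Whitney) formula, which
#' handles tied scores exactly. ROC points are generated at every distinct
#' score threshold (predicted positive when `score >= threshold`) plus the
#' two endpoints.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels logical labels; both classes must be present.
#' @return list of class `roc_curve` with `points` (data frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores)
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !labels) / nn, tpr = sum(pred & labels) / np)
  }, numeric(2))
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, pts["fpr", ]),
                       tpr = c(0, pts["tpr", ]))
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1)
    points <- rbind(points, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f over %d thresholds\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Reconstructed grade-by-outcome contingency table
#'
#' The packaged 126-patient distribution of patients with and without a
#' functionally significant stenosis across the five CCTA stenosis grades:
#' per grade `(positive, negative)` = (0,2), (0,8), (6,4), (61,30), (14,1);
#' 81 positives and 45 negatives in total, with no positives below 25
#' percent stenosis.
#'
#' @return data frame of class `ordinal_contingency` with columns `grade`,
#'   `positives`, `negatives`.
#' @export
build_ordinal_fixture <- function() {
  structure(data.frame(grade = grade_levels,
                       positives = c(0L, 0L, 6L, 61L, 14L),
                       negatives = c(2L, 8L, 4L, 30L, 1L),
                       stringsAsFactors = FALSE),
            class = c("ordinal_contingency", "data.frame"))
}

#' Expand an ordinal contingency table into scores and labels
#'
#' @param table an [build_ordinal_fixture()]-style data frame.
#' @return list with `scores` (ordinal 0..4 per patient) and `labels`.
#' @export
contingency_to_scores <- function(table) {
  scores <- rep(seq_len(nrow(table)) - 1,
                times = table$positives + table$negatives)
  labels <- unlist(lapply(seq_len(nrow(table)), function(i)
    c(rep(TRUE, table$positives[i]), rep(FALSE, table$negatives[i]))))
  list(scores = scores, labels = as.logical(labels))
}

#' Threshold an ordinal contingency table into confusion counts
#'
#' Predicts positive for every patient at or above `min_grade`.
#'
#' @param table contingency table.
#' @param min_grade grade token at which predictions turn positive
#'   (e.g. `"G3"` for the "at least 50 percent stenosis" reading).
#' @return a [confusion_counts()].
#' @export
contingency_counts <- function(table, min_grade) {
  i <- match(min_grade, table$grade)
  if (is.na(i)) stop("unknown grade ", min_grade)
  pred <- seq_len(nrow(table)) >= i
  structure(list(tp = sum(table$positives[pred]),
                 fp = sum(table$negatives[pred]),
                 tn = sum(table$negatives[!pred]),
                 fn = sum(table$positives[!pred])),
            class = "confusion_counts")
}

#' Drop patients with prior cardiac events
#'
#' Sensitivity-analysis filter: removes records flagged with a prior
#' myocardial infarction, PCI or CABG.
#'
#' @param records list of patient records.
#' @param exclude_prior_events logical; `FALSE` returns the input unchanged.
#' @return filtered record list.
#' @export
subgroup_filter <- function(records, exclude_prior_events = TRUE) {
  if (!exclude_prior_events) return(records)
  Filter(function(r) !isTRUE(r$prior_event), records)
}

#' Cross-validation plan
#'
#' @param k number of folds.
#' @param repetitions number of repeated CV experiments.
#' @param stratified preserve class proportions per fold (within one
#'   patient).
#' @param seed master seed; each repetition derives its own fold
#'   randomization from it.
#' @param rerandomize draw new folds each repetition (`FALSE` reuses the
#'   first split, making across-repetition SDs collapse to 0).
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(k = 10L, repetitions = 50L, stratified = TRUE, seed = 1L,
                    rerandomize = TRUE) {
  structure(list(k = as.integer(k), repetitions = as.integer(repetitions),
                 stratified = isTRUE(stratified), seed = as.integer(seed),
                 rerandomize = isTRUE(rerandomize)),
            class = "cv_plan")
}

# Stratified fold assignment: shuffle within class, deal round-robin.
# Guarantees per-fold class counts within one patient of proportionality.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

#' Repeated stratified cross-validation of the combined triage method
#'
#' For every repetition, the intermediate-grade patients are split into `k`
#' stratified folds; the SVM is trained on the training folds' intermediates
#' only and produces exactly one out-of-fold probability per intermediate
#' patient. Extreme-grade patients enter each repetition's evaluation with
#' triage probabilities 0/1. Per repetition the combined ROC/AUC over all
#' patients and the binary metrics at `threshold` are computed; the
#' aggregate reports mean and SD across repetitions.
#'
#' @param features feature matrix/data frame for all patients (rows in
#'   `records` order; extreme patients' rows may be arbitrary, they are
#'   never used).
#' @param labels logical reference-standard labels for all patients.
#' @param groups triage groups per patient (`non_significant`,
#'   `intermediate`, `significant`).
#' @param plan a [cv_plan()].
#' @param svm_config configuration passed to [train_classifier()].
#' @param threshold probability operating point for the binary metrics.
#' @return Object of class `repeated_cv`: `per_repetition` data frame
#'   (auc, sensitivity, specificity, ppv, npv, accuracy), `aggregate`
#'   (mean/sd per metric), `probabilities` (patients x repetitions matrix
#'   of combined probabilities), and the plan.
#' @export
run_repeated_cv <- function(features, labels, groups, plan = cv_plan(),
                            svm_config = list(), threshold = 0.5) {
  x <- as_feature_matrix(features)
  labels <- as.logical(labels)
  n <- length(labels)
  stopifnot(nrow(x) == n, length(groups) == n)
  inter <- which(groups == "intermediate")
  if (length(inter) == 0) stop("no intermediate-grade patients to cross-validate")
  yint <- labels[inter]
  if (min(table(yint)) < plan$k)
    stop(sprintf(
      "stratification impossible: smallest class among intermediates has %d patients < k = %d folds",
      min(table(yint)), plan$k))
  base_prob <- ifelse(groups == "significant", 1,
                      ifelse(groups == "non_significant", 0, NA_real_))
  probs <- matrix(NA_real_, n, plan$repetitions)
  rows <- vector("list", plan$repetitions)
  for (rep_i in seq_len(plan$repetitions)) {
    fold_seed <- if (plan$rerandomize) derive_seed(plan$seed, rep_i) else
      derive_seed(plan$seed, 1L)
    folds <- stratified_folds(yint, plan$k, fold_seed)
    p <- base_prob
    for (f in seq_len(plan$k)) {
      val <- inter[folds == f]
      tr <- inter[folds != f]
      cfg <- utils::modifyList(list(seed = derive_seed(fold_seed, f)), svm_config)
      model <- train_classifier(x[tr, , drop = FALSE], labels[tr], cfg)
      p[val] <- predict_probability(model, x[val, , drop = FALSE])
    }
    stopifnot(!anyNA(p))
    probs[, rep_i] <- p
    roc <- roc_auc(p, labels)
    met <- diagnostic_metrics(confusion_counts(p > threshold, labels))
    rows[[rep_i]] <- data.frame(
      repetition = rep_i, auc = roc$auc,
      sensitivity = met$sensitivity$estimate,
      specificity = met$specificity$estimate,
      ppv = met$ppv$estimate, npv = met$npv$estimate,
      accuracy = met$accuracy$estimate)
  }
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep), "repetition")
  aggregate <- lapply(metrics, function(m)
    c(mean = mean(per_rep[[m]]), sd = stats::sd(per_rep[[m]])))
  names(aggregate) <- metrics
  structure(list(per_repetition = per_rep, aggregate = aggregate,
                 probabilities = probs, plan = plan, threshold = threshold),
            class = "repeated_cv")
}

#' @export
print.repeated_cv <- function(x, ...) {
  cat(sprintf("<repeated_cv> %d repetitions of %d-fold stratified CV (seed %d)\n",
              x$plan$repetitions, x$plan$k, x$plan$seed))
  for (m in names(x$aggregate))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m,
                x$aggregate[[m]]["mean"], x$aggregate[[m]]["sd"]))
  invisible(x)
}

#' Write ROC points to a TSV file
#'
#' @param roc a [roc_auc()] result.
#' @param path output path.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
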