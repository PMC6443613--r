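test_that("the reference rule applies FFR <= 0.80 or ICA DS >= 90 inclusively", {
  rec <- function(ffr, ica) list(patient_id = "X", ffr_values = ffr,
                                 ica_ds_percent = ica)
  expect_false(reference_label(rec(0.82, 80)))
  expect_true(reference_label(rec(c(0.85, 0.92), c(40, 92))))
  expect_true(reference_label(rec(0.80, 10)))          # inclusive boundary
  expect_false(reference_label(rec(0.801, NA)))
  expect_true(reference_label(rec(NA, 90)))            # inclusive boundary
  expect_error(reference_label(rec(NA_real_, NA_real_)), "physiology")
})

test_that("confusion counts add up and reject mismatched lengths", {
  cc <- confusion_counts(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]), c(tp = 3, fp = 0, tn = 2, fn = 0))
  cc2 <- confusion_counts(rep(TRUE, 5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(unlist(cc2[c("tp", "fp", "tn", "fn")]), c(tp = 3, fp = 2, tn = 0, fn = 0))
  expect_error(confusion_counts(TRUE, c(TRUE, FALSE)), "length")
})

test_that("the reconstructed contingency table has the published margins", {
  tab <- build_ordinal_fixture()
  expect_equal(sum(tab$positives), 81L)
  expect_equal(sum(tab$negatives), 45L)
  expect_equal(tab$positives + tab$negatives, c(2L, 8L, 10L, 91L, 15L))
  expect_equal(tab$positives[tab$grade %in% c("G0", "G1")], c(0L, 0L))
  cc <- contingency_counts(tab, "G3")
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 75, fp = 31, tn = 14, fn = 6))
})

test_that("diagnostic metrics carry exact binomial intervals and honest NAs", {
  m <- diagnostic_metrics(contingency_counts(build_ordinal_fixture(), "G3"))
  expect_equal(round(100 * m$sensitivity$estimate, 1), 92.6)
  expect_equal(round(100 * m$specificity$estimate, 1), 31.1)
  # the Clopper-Pearson interval matches binom.test exactly
  ci <- stats::binom.test(75, 81)$conf.int
  expect_equal(m$sensitivity$lower, ci[1])
  expect_equal(m$sensitivity$upper, ci[2])
  expect_true(m$sensitivity$lower <= m$sensitivity$estimate &&
                m$sensitivity$estimate <= m$sensitivity$upper)
  z <- diagnostic_metrics(confusion_counts(logical(0), logical(0)))
  for (nm in names(z)) expect_true(is.na(z[[nm]]$estimate))
})

test_that("AUC equals both brute-force concordance and the trapezoidal integral", {
  trapezoid <- function(pts) {
    o <- order(pts$fpr, pts$tpr)
    sum(diff(pts$fpr[o]) * (head(pts$tpr[o], -1) + tail(pts$tpr[o], -1)) / 2)
  }
  concordance <- function(scores, labels) {
    pos <- scores[labels]
    neg <- scores[!labels]
    total <- 0
    for (p in pos) for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
  }
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    roc <- roc_auc(scores, labels)
    expect_equal(roc$auc, concordance(scores, labels), tolerance = 1e-12)
    expect_equal(roc$auc, trapezoid(roc$points), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation and handles extremes", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- c(rnorm(30, 1), rnorm(25, 0))
  labels <- rep(c(TRUE, FALSE), c(30, 25))
  got <- roc_auc(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T))$auc, 1.0)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("the ordinal DS-only AUC of the reconstructed cohort is 0.68", {
  sc <- contingency_to_scores(build_ordinal_fixture())
  expect_equal(round(roc_auc(sc$scores, sc$labels)$auc, 2), 0.68)
})

test_that("permuted labels give a null AUC centred on one half", {
  set.seed(13)
  scores <- rnorm(60)
  labels <- rep(c(TRUE, FALSE), 30)
  aucs <- replicate(1000, roc_auc(scores, sample(labels))$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("the subgroup filter removes exactly the flagged patients", {
  spec <- cohort_spec(seed = 3)
  co <- generate_cohort(spec, volumes = FALSE)
  flagged <- sum(vapply(co$records, `[[`, logical(1), "prior_event"))
  expect_equal(flagged, 23L)
  kept <- subgroup_filter(co$records, exclude_prior_events = TRUE)
  expect_length(kept, 103L)
  expect_identical(subgroup_filter(co$records, FALSE), co$records)
  expect_length(subgroup_filter(list(), TRUE), 0L)
})

test_that("stratified folds partition patients with balanced classes", {
  labels <- rep(c(TRUE, FALSE), c(67, 34))
  folds <- lvmtriage:::stratified_folds(labels, 10, seed = 5)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(length(folds), 101)
  per_fold_pos <- tapply(labels, folds, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
  per_fold_n <- table(folds)
  expect_lte(diff(range(per_fold_n)), 2)  # within one patient per class
})

test_that("repeated CV validates every intermediate exactly once per repetition", {
  set.seed(14)
  n <- 40
  x <- matrix(rnorm(n * 4), n, 4)
  labels <- x[, 1] > 0
  groups <- rep("intermediate", n)
  groups[1:4] <- c("significant", "significant", "non_significant",
                   "non_significant")
  labels[1:4] <- c(TRUE, TRUE, FALSE, FALSE)
  plan <- cv_plan(k = 5, repetitions = 4, seed = 2)
  cv <- run_repeated_cv(x, labels, groups, plan, svm_config = list(cost_grid = 1))
  expect_equal(nrow(cv$per_repetition), 4)
  expect_false(anyNA(cv$probabilities))
  # extremes carry their triage probabilities in every repetition
  expect_true(all(cv$probabilities[1:2, ] == 1))
  expect_true(all(cv$probabilities[3:4, ] == 0))
  # determinism
  cv2 <- run_repeated_cv(x, labels, groups, plan, svm_config = list(cost_grid = 1))
  expect_identical(cv$per_repetition, cv2$per_repetition)
  # repetitions differ when folds are rerandomized
  expect_gt(stats::sd(cv$per_repetition$auc), 0)
})

test_that("suppressing rerandomization collapses the across-repetition SD to zero", {
  set.seed(15)
  n <- 30
  x <- matrix(rnorm(n * 3), n, 3)
  labels <- rep(c(TRUE, FALSE), 15)
  groups <- rep("intermediate", n)
  plan <- cv_plan(k = 5, repetitions = 3, seed = 9, rerandomize = FALSE)
  cv <- run_repeated_cv(x, labels, groups, plan, svm_config = list(cost_grid = 1))
  expect_equal(unname(cv$aggregate$auc["sd"]), 0)
})

test_that("impossible stratification is rejected with a clear message", {
  x <- matrix(rnorm(20 * 2), 20, 2)
  labels <- c(rep(TRUE, 17), rep(FALSE, 3))
  expect_error(run_repeated_cv(x, labels, rep("intermediate", 20),
                               cv_plan(k = 10, repetitions = 1)),
               "stratification impossible")
})
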