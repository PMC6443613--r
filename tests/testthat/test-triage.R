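test_that("the patient-level maximum grade ignores non-diagnostic vessels", {
  expect_equal(patient_max_grade(c("G1", "G3", "ND")), "G3")
  expect_equal(patient_max_grade("G0"), "G0")
  expect_equal(patient_max_grade(c("ND", "ND")), "ND")
  expect_equal(patient_max_grade(c("G4", "G2")), "G4")
  expect_error(patient_max_grade(character(0)), "at least one")
  expect_error(patient_max_grade(c("G1", "80%")), "unknown")
})

test_that("triage groups follow the grade bands", {
  expect_equal(triage_group("G0"), "non_significant")
  expect_equal(triage_group("G1"), "non_significant")
  expect_equal(triage_group("G2"), "intermediate")
  expect_equal(triage_group("G3"), "intermediate")
  expect_equal(triage_group("G4"), "significant")
  expect_error(triage_group("ND"), "non-diagnostic")
  expect_true(is.na(triage_group("ND", nd_action = "exclude")))
})

test_that("combined probabilities force extremes to 0/1 and pass intermediates", {
  expect_identical(combined_probability("non_significant"), 0.0)
  expect_identical(combined_probability("significant"), 1.0)
  expect_identical(combined_probability("intermediate", 0.37), 0.37)
  expect_error(combined_probability("intermediate"), "require")
  expect_error(combined_probability("non_significant", 0.4), "ignores image")
  expect_error(combined_probability("significant", 0.9), "ignores image")
  expect_error(combined_probability("intermediate", 1.2), "\\[0, 1\\]")
})

test_that("triage operations are pure and idempotent", {
  for (g in c("G0", "G2", "G4")) {
    expect_identical(triage_group(g), triage_group(g))
  }
  grades <- c("G2", "ND", "G3")
  expect_identical(patient_max_grade(grades), patient_max_grade(grades))
  expect_identical(grades, c("G2", "ND", "G3"))  # input untouched
  expect_identical(combined_probability("intermediate", 0.5),
                   combined_probability("intermediate", 0.5))
})

test_that("triage_cohort assembles results and flags all-ND patients", {
  records <- list(
    list(patient_id = "A", vessel_grades = c("G1", "G0")),
    list(patient_id = "B", vessel_grades = c("G3", "ND")),
    list(patient_id = "C", vessel_grades = "G4"),
    list(patient_id = "D", vessel_grades = c("ND", "ND")))
  out <- triage_cohort(records, classifier_probs = c(B = 0.42))
  expect_equal(out$excluded, "D")
  res <- out$results
  expect_equal(res$probability[res$patient_id == "A"], 0)
  expect_equal(res$probability[res$patient_id == "B"], 0.42)
  expect_equal(res$probability[res$patient_id == "C"], 1)
  expect_equal(res$source[res$patient_id == "B"], "classifier")
  expect_equal(res$source[res$patient_id == "C"], "grade_rule")
  expect_error(triage_cohort(records, classifier_probs = numeric()),
               "intermediate patient B")
})
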