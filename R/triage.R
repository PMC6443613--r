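# Stenosis-degree category model and the combined triage rule: patients
# with extreme CCTA grades are decided by the grade alone, intermediates
# are deferred to the learned classifier.

#' CCTA stenosis grade vocabulary
#'
#' Five ordered diagnostic categories of maximum per-vessel degree of
#' stenosis — `G0` (0%), `G1` (1-24%), `G2` (25-49%), `G3` (50-69%),
#' `G4` (>= 70%) — plus the unordered token `ND` (non-diagnostic segment).
#'
#' @format `grade_levels` is the ordered character vector of diagnostic
#'   grades; `grade_percent` maps each grade to its percent-stenosis band.
#' @export
grade_levels <- c("G0", "G1", "G2", "G3", "G4")

#' @rdname grade_levels
#' @export
grade_percent <- c(G0 = "0%", G1 = "1-24%", G2 = "25-49%", G3 = "50-69%",
                   G4 = ">=70%", ND = "non-diagnostic")

# ordinal rank of a diagnostic grade; NA for ND
grade_rank <- function(grade) {
  r <- match(grade, grade_levels)
  r
}

validate_grades <- function(grades) {
  bad <- !grades %in% c(grade_levels, "ND")
  if (any(bad))
    stop("unknown stenosis grade token(s): ",
         paste(unique(grades[bad]), collapse = ", "))
  grades
}

#' Patient-level maximum stenosis grade
#'
#' The maximum over the patient's diagnostic vessel grades; non-diagnostic
#' (`ND`) vessels are ignored whenever any diagnostic grade exists. A
#' patient whose every vessel is `ND` yields `"ND"` (to be flagged for
#' exclusion, mirroring image-quality exclusion).
#'
#' @param vessel_grades non-empty character vector of grades
#'   (`G0..G4`, `ND`).
#' @return A single grade token.
#' @export
patient_max_grade <- function(vessel_grades) {
  if (length(vessel_grades) == 0) stop("at least one vessel grade is required")
  validate_grades(vessel_grades)
  r <- grade_rank(vessel_grades)
  if (all(is.na(r))) return("ND")
  grade_levels[max(r, na.rm = TRUE)]
}

#' Triage group of a maximum stenosis grade
#'
#' Maps the patient's maximum CCTA grade to the triage group: grades up to
#' 24% (`G0`, `G1`) are non-significant, 25-69% (`G2`, `G3`) intermediate,
#' and at least 70% (`G4`) significant. `ND` has no triage group and is
#' rejected unless `nd_action = "exclude"`, which returns `NA` so callers
#' can drop the patient explicitly.
#'
#' @param grade a single grade token.
#' @param nd_action `"error"` (default) or `"exclude"`.
#' @return One of `"non_significant"`, `"intermediate"`, `"significant"`
#'   (or `NA` for excluded `ND`).
#' @export
triage_group <- function(grade, nd_action = c("error", "exclude")) {
  nd_action <- match.arg(nd_action)
  validate_grades(grade)
  stopifnot(length(grade) == 1)
  if (grade == "ND") {
    if (nd_action == "error")
      stop("all vessels non-diagnostic: no triage group (use nd_action = \"exclude\")")
    return(NA_character_)
  }
  switch(grade,
         G0 = "non_significant", G1 = "non_significant",
         G2 = "intermediate", G3 = "intermediate",
         G4 = "significant")
}

#' Combined probability under the triage rule
#'
#' Patients graded non-significant or significant by CCTA are assigned
#' probabilities 0 and 1; intermediate patients receive the classifier's
#' probability unchanged. Supplying a classifier probability for an extreme
#' group (or omitting it for an intermediate) is rejected, guarding against
#' silent misuse.
#'
#' @param group triage group token.
#' @param classifier_prob probability in `[0, 1]`; required iff `group` is
#'   `"intermediate"`.
#' @return Probability in `[0, 1]`.
#' @export
combined_probability <- function(group, classifier_prob = NULL) {
  stopifnot(group %in% c("non_significant", "intermediate", "significant"))
  if (group == "intermediate") {
    if (is.null(classifier_prob) || is.na(classifier_prob))
      stop("intermediate-grade patients require a classifier probability")
    if (classifier_prob < 0 || classifier_prob > 1)
      stop("`classifier_prob` must lie in [0, 1]")
    return(as.numeric(classifier_prob))
  }
  if (!is.null(classifier_prob))
    stop("classifier probability supplied for a grade-decided patient (group '",
         group, "'): the triage rule ignores image content for extremes")
  if (group == "non_significant") 0.0 else 1.0
}

#' Triage a cohort of patient records
#'
#' Applies [patient_max_grade()], [triage_group()] and
#' [combined_probability()] across a cohort. All-`ND` patients are excluded
#' and reported.
#'
#' @param records list of patient records (see [generate_cohort()]).
#' @param classifier_probs named numeric vector of classifier probabilities
#'   for the intermediate patients (names = patient ids).
#' @return A list with `results` — a data frame `patient_id`, `max_grade`,
#'   `group`, `probability`, `source` — and `excluded` (all-`ND` ids).
#' @export
triage_cohort <- function(records, classifier_probs = numeric()) {
  rows <- lapply(records, function(r) {
    mg <- patient_max_grade(r$vessel_grades)
    grp <- triage_group(mg, nd_action = "exclude")
    if (is.na(grp))
      return(data.frame(patient_id = r$patient_id, max_grade = mg,
                        group = NA_character_, probability = NA_real_,
                        source = NA_character_, stringsAsFactors = FALSE))
    if (grp == "intermediate") {
      if (!r$patient_id %in% names(classifier_probs))
        stop("no classifier probability for intermediate patient ", r$patient_id)
      p <- classifier_probs[[r$patient_id]]
      data.frame(patient_id = r$patient_id, max_grade = mg, group = grp,
                 probability = combined_probability(grp, p),
                 source = "classifier", stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = r$patient_id, max_grade = mg, group = grp,
                 probability = combined_probability(grp),
                 source = "grade_rule", stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  list(results = res[!is.na(res$group), , drop = FALSE],
       excluded = res$patient_id[is.na(res$group)])
}
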