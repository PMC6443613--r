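# Synthetic cohort metadata: stenosis grades, invasive physiology, labels.

# Per-grade probability that a patient is positive, used to allocate the
# requested number of positives across grade categories. No positives occur
# below 25% DS; the higher grades carry increasing positive fractions.
default_grade_pos_weight <- c(G0 = 0, G1 = 0, G2 = 0.6, G3 = 61 / 91, G4 = 14 / 15)

grade_ds_range <- list(G0 = c(0, 4), G1 = c(5, 24), G2 = c(25, 49),
                       G3 = c(50, 69), G4 = c(70, 89))

# Largest-remainder allocation of `total` positives to categories with sizes
# `counts` and weights `w`, capped by category size, exact by construction.
allocate_positives <- function(counts, total, w = default_grade_pos_weight) {
  target <- counts * w
  base <- pmin(floor(target), counts)
  room <- counts - base
  rem <- total - sum(base)
  if (rem < 0) {
    # too many floored positives: remove from lowest-weight eligible grades
    for (g in order(w)) {
      take <- min(base[g], -rem)
      base[g] <- base[g] - take
      rem <- rem + take
      if (rem >= 0) break
    }
  } else if (rem > 0) {
    frac <- target - floor(target)
    ord <- order(frac, w, decreasing = TRUE)
    for (g in ord) {
      if (rem == 0) break
      add <- min(room[g], rem)
      if (w[g] == 0) next
      base[g] <- base[g] + add
      rem <- rem - add
    }
  }
  if (sum(base) != total)
    stop("cannot allocate the requested number of positives to the requested grade composition")
  as.integer(base)
}

#' Simulate invasive physiology consistent with a patient label
#'
#' Draws per-vessel invasive FFR values and invasive-angiography stenosis
#' percentages such that applying the reference rule (any FFR at or below
#' 0.80, or any ICA diameter stenosis of at least 90 percent) reproduces
#' `label`. Positive patients are realized through the FFR pathway with
#' probability `ffr_path_prob` (minimum FFR drawn uniformly on
#' `[0.55, 0.80]`) and otherwise through an angiographic high-grade stenosis
#' (ICA DS on `[90, 99]`, all FFR above 0.80, FFR not measured in the
#' high-grade vessel). Negative patients have all FFR on `[0.82, 0.95]` and
#' all ICA DS below 90.
#'
#' @param label logical ground-truth label.
#' @param grades character vector of per-vessel CCTA grades
#'   (`G0..G4` or `ND`), at least one vessel.
#' @param seed integer seed.
#' @param ffr_path_prob probability a positive is realized via FFR.
#' @return list with numeric `ffr` and `ica_ds` per vessel (`NA` = not
#'   measured; ICA is always measured).
#' @export
assign_physiology <- function(label, grades, seed, ffr_path_prob = 0.85) {
  nv <- length(grades)
  if (nv < 1) stop("at least one vessel is required")
  with_seed(seed, {
    rank <- grade_rank(grades)
    rank[is.na(rank)] <- -1L
    culprit <- which.max(rank)
    ica <- vapply(grades, function(g) {
      r <- grade_ds_range[[if (g == "ND") sample(names(grade_ds_range), 1) else g]]
      stats::runif(1, r[1], r[2])
    }, numeric(1))
    ica <- unname(pmin(ica, 89))
    ffr <- stats::runif(nv, 0.82, 0.95)
    # FFR occasionally not measured in clearly normal vessels
    skip <- stats::runif(nv) < 0.3 & seq_len(nv) != culprit
    ffr[skip] <- NA_real_
    if (isTRUE(label)) {
      if (stats::runif(1) < ffr_path_prob) {
        ffr[culprit] <- stats::runif(1, 0.55, 0.80)
      } else {
        ica[culprit] <- stats::runif(1, 90, 99)
        ffr[culprit] <- NA_real_  # high-grade vessels are not wired
      }
    }
    list(ffr = ffr, ica_ds = ica)
  })
}

#' Generate a reproducible synthetic cohort
#'
#' Builds `spec$n_patients` patient records with per-vessel CCTA stenosis
#' grades matching `spec$category_counts` exactly (each patient's maximum
#' grade is their category), invasive physiology consistent with the
#' reference rule, prior-event flags, and — unless `volumes = FALSE` — one
#' phantom CT volume plus true myocardium mask per patient. Everything is a
#' deterministic function of `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory; when given, volumes and masks are
#'   written as NIfTI (`<id>.nii.gz`, `<id>_mask.nii.gz`) and the cohort
#'   table as `cohort.csv`. Nothing is written for an inconsistent spec.
#' @param volumes logical; generate image volumes (set `FALSE` for
#'   metadata-only cohorts).
#' @return An object of class `synthetic_cohort`: list with `records` (list
#'   of patient records), `table` (one row per vessel), and, when requested,
#'   `volumes` and `masks` (named lists).
#' @export
generate_cohort <- function(spec, dir = NULL, volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  n_pos <- as.integer(round(spec$prevalence * n))
  if (n == 0) {
    out <- structure(list(records = list(),
                          table = empty_cohort_table(),
                          volumes = NULL, masks = NULL, spec = spec),
                     class = "synthetic_cohort")
    return(out)
  }
  counts <- spec$category_counts
  if (is.null(counts)) {
    counts <- with_seed(derive_seed(spec$seed, 1L), {
      g <- sample(1:5, n, replace = TRUE, prob = c(2, 8, 10, 91, 15))
      tabulate(g, 5)
    })
  }
  pos_per_cat <- allocate_positives(counts, n_pos)
  categories <- rep(grade_levels, times = counts)
  labels <- unlist(lapply(1:5, function(g)
    c(rep(TRUE, pos_per_cat[g]), rep(FALSE, counts[g] - pos_per_cat[g]))))
  # deterministic shuffle of patient order
  ord <- with_seed(derive_seed(spec$seed, 2L), sample.int(n))
  categories <- categories[ord]
  labels <- labels[ord]
  n_prior <- as.integer(round(spec$prior_event_rate * n))
  prior <- logical(n)
  prior[with_seed(derive_seed(spec$seed, 3L), sample.int(n, n_prior))] <- TRUE

  records <- vector("list", n)
  vols <- if (volumes) vector("list", n) else NULL
  masks <- if (volumes) vector("list", n) else NULL
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    pseed <- derive_seed(spec$seed, 100L + i)
    vgrades <- with_seed(pseed, {
      nv <- sample(1:3, 1)
      g <- character(nv)
      g[1] <- categories[i]
      if (nv > 1) {
        cat_rank <- grade_rank(categories[i])
        g[-1] <- grade_levels[sample.int(cat_rank, nv - 1, replace = TRUE)]
        # occasionally one non-maximal vessel is non-diagnostic
        if (nv > 1 && stats::runif(1) < 0.15) g[nv] <- "ND"
      }
      g
    })
    phys <- assign_physiology(labels[i], vgrades, derive_seed(pseed, 1L),
                              spec$ffr_path_prob)
    records[[i]] <- list(
      patient_id = pid, vessel_grades = vgrades,
      ffr_values = phys$ffr, ica_ds_percent = phys$ica_ds,
      prior_event = prior[i], true_label = labels[i],
      category = categories[i]
    )
    if (volumes) {
      pp <- phantom_params(spec, derive_seed(pseed, 2L))
      ph <- generate_phantom_volume(pp, labels[i], spec)
      vols[[i]] <- ph$volume
      masks[[i]] <- ph$mask
    }
  }
  ids <- vapply(records, `[[`, character(1), "patient_id")
  if (volumes) {
    names(vols) <- ids
    names(masks) <- ids
  }
  tab <- cohort_records_to_table(records)
  out <- structure(list(records = records, table = tab,
                        volumes = vols, masks = masks, spec = spec),
                   class = "synthetic_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_table(tab, file.path(dir, "cohort.csv"))
    if (volumes) {
      for (pid in ids) {
        write_volume(vols[[pid]], file.path(dir, paste0(pid, ".nii.gz")))
        write_mask(masks[[pid]], file.path(dir, paste0(pid, "_mask.nii.gz")),
                   spec$voxel_spacing)
      }
    }
  }
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n <- length(x$records)
  npos <- sum(vapply(x$records, `[[`, logical(1), "true_label"))
  cat(sprintf("<synthetic_cohort> %d patients (%d positive), %s\n", n, npos,
              if (is.null(x$volumes)) "metadata only" else "with phantom volumes"))
  invisible(x)
}

empty_cohort_table <- function() {
  data.frame(patient_id = character(), vessel_id = integer(),
             ccta_grade = character(), ffr = numeric(),
             ica_ds_percent = numeric(), prior_event = logical(),
             true_label = logical(), stringsAsFactors = FALSE)
}

cohort_records_to_table <- function(records) {
  if (length(records) == 0) return(empty_cohort_table())
  do.call(rbind, lapply(records, function(r) {
    nv <- length(r$vessel_grades)
    data.frame(patient_id = r$patient_id, vessel_id = seq_len(nv),
               ccta_grade = r$vessel_grades,
               ffr = round(r$ffr_values, 4),
               ica_ds_percent = round(r$ica_ds_percent, 1),
               prior_event = r$prior_event, true_label = r$true_label,
               stringsAsFactors = FALSE)
  }))
}

#' Write / read a per-vessel cohort table
#'
#' The CSV schema has one row per vessel: `patient_id`, `vessel_id`,
#' `ccta_grade` (tokens `G0, G1, G2, G3, G4, ND`), `ffr` (empty = not
#' measured), `ica_ds_percent`, `prior_event`, `true_label`.
#'
#' @param table data frame in the schema above.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a per-vessel cohort table into patient records
#'
#' Rows are grouped by `patient_id` (in first-appearance order); empty
#' `ffr`/`ica_ds_percent` cells become `NA` ("not measured"). Unknown grade
#' tokens and duplicated `(patient_id, vessel_id)` pairs are rejected with
#' the offending row number.
#'
#' @param path CSV path in the cohort schema.
#' @return list of patient records (as produced by [generate_cohort()]).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  required <- c("patient_id", "vessel_id", "ccta_grade", "ffr",
                "ica_ds_percent", "prior_event", "true_label")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!tab$ccta_grade %in% c(grade_levels, "ND"))
  if (length(bad))
    stop(sprintf("row %d: unknown stenosis grade token '%s' (expected %s)",
                 bad[1], tab$ccta_grade[bad[1]],
                 paste(c(grade_levels, "ND"), collapse = ", ")))
  key <- paste(tab$patient_id, tab$vessel_id)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("row %d: duplicate (patient_id, vessel_id) pair '%s'",
                 dup[1], key[dup[1]]))
  ids <- unique(tab$patient_id)
  lapply(ids, function(pid) {
    rows <- tab[tab$patient_id == pid, , drop = FALSE]
    rows <- rows[order(rows$vessel_id), , drop = FALSE]
    list(patient_id = pid,
         vessel_grades = rows$ccta_grade,
         ffr_values = as.numeric(rows$ffr),
         ica_ds_percent = as.numeric(rows$ica_ds_percent),
         prior_event = as.logical(rows$prior_event[1]),
         true_label = as.logical(rows$true_label[1]),
         category = patient_max_grade(rows$ccta_grade))
  })
}
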