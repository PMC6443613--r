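# Patient-level features: statistics per encoding dimension.

feature_stat_funs <- list(
  mean = function(x) mean(x),
  sd   = function(x) stats::sd(x),
  min  = function(x) min(x),
  p25  = function(x) unname(stats::quantile(x, 0.25, type = 7)),
  p50  = function(x) unname(stats::quantile(x, 0.50, type = 7)),
  p75  = function(x) unname(stats::quantile(x, 0.75, type = 7)),
  max  = function(x) max(x)
)

#' Collapse voxel encodings into one patient feature vector
#'
#' Computes the requested statistics independently for every encoding
#' dimension and concatenates them in dimension-major order
#' (`dim01_mean, dim01_sd, ..., dim02_mean, ...`). The result is invariant
#' to the ordering of voxels. The default statistic set — mean, standard
#' deviation, minimum, the quartiles and maximum — summarizes location,
#' scale and extremes of each encoding dimension; percentiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param encodings a [encode_lvm()] `voxel_encoding_set`, or an
#'   `m x d` matrix of per-voxel encodings.
#' @param statistics ordered subset of
#'   `c("mean", "sd", "min", "p25", "p50", "p75", "max")`.
#' @param patient_id optional provenance tag (taken from the encoding set
#'   when present).
#' @return Named numeric vector of class `patient_features`, length
#'   `d * length(statistics)`, with attributes `patient_id`, `statistics`
#'   and `encoding_dim`. A single-voxel set yields `sd = 0`.
#' @export
summarize_encodings <- function(encodings,
                                statistics = c("mean", "sd", "min", "p25",
                                               "p50", "p75", "max"),
                                patient_id = NULL) {
  if (inherits(encodings, "voxel_encoding_set")) {
    patient_id <- patient_id %||% encodings$patient_id
    encodings <- encodings$encodings
  }
  encodings <- as.matrix(encodings)
  if (nrow(encodings) == 0) stop("empty encoding set: no voxels to summarize")
  if (length(statistics) < 1) stop("at least one statistic is required")
  unknown <- setdiff(statistics, names(feature_stat_funs))
  if (length(unknown))
    stop("unknown statistics: ", paste(unknown, collapse = ", "))
  d <- ncol(encodings)
  vals <- numeric(d * length(statistics))
  nms <- character(length(vals))
  at <- 0L
  for (k in seq_len(d)) {
    col <- encodings[, k]
    for (s in statistics) {
      at <- at + 1L
      v <- feature_stat_funs[[s]](col)
      vals[at] <- if (is.na(v) && s == "sd") 0 else v   # single voxel: sd -> 0
      nms[at] <- sprintf("dim%02d_%s", k, s)
    }
  }
  if (any(!is.finite(vals))) stop("non-finite feature values")
  structure(stats::setNames(vals, nms), class = "patient_features",
            patient_id = patient_id, statistics = statistics,
            encoding_dim = d)
}

#' @export
print.patient_features <- function(x, ...) {
  cat(sprintf("<patient_features> %d values = %d dims x %d statistics (patient %s)\n",
              length(x), attr(x, "encoding_dim"),
              length(attr(x, "statistics")),
              attr(x, "patient_id") %||% "?"))
  utils::str(unclass(x))
  invisible(x)
}

#' Assemble a per-patient feature table
#'
#' @param feature_list named list of `patient_features` vectors with
#'   identical layout.
#' @return data frame with one row per patient, a `patient_id` column and
#'   one named column per feature.
#' @export
feature_table <- function(feature_list) {
  stopifnot(length(feature_list) >= 1)
  mat <- do.call(rbind, lapply(feature_list, as.numeric))
  colnames(mat) <- names(feature_list[[1]])
  ids <- vapply(seq_along(feature_list), function(i)
    attr(feature_list[[i]], "patient_id") %||% names(feature_list)[i] %||%
      as.character(i), character(1))
  data.frame(patient_id = ids, mat, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}
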