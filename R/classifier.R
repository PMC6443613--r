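# Patient classification: RBF-kernel SVM over patient feature vectors with
# leakage-safe standardization and Platt-style probability calibration.

#' Train the patient-level SVM classifier
#'
#' Fits a support vector machine mapping patient feature vectors to the
#' probability of a functionally significant stenosis. Features are
#' standardized with training-set statistics (stored in the model and
#' re-applied at prediction time), the regularization constant is chosen by
#' an inner stratified grid search on the training data only, class
#' imbalance is handled by inverse-prevalence class weights, and a
#' Platt-style sigmoid is fitted to the training decision values so the
#' triage rule can consume calibrated probabilities. The fit is
#' deterministic given `config$seed`.
#'
#' @param features numeric matrix (patients x features), a data frame from
#'   [feature_table()], or a list of `patient_features`.
#' @param labels logical vector; both classes must be present.
#' @param config named list overriding: `kernel` ("radial"), `cost_grid`
#'   (c(0.1, 1, 10); a single value skips the search), `gamma` (default
#'   `1/ncol`), `inner_k` (3 inner folds), `seed` (1).
#' @return An object of class `stenosis_svm` holding the fitted SVM, the
#'   per-feature center/scale, the Platt calibration coefficients and the
#'   training configuration.
#' @export
train_classifier <- function(features, labels, config = list()) {
  cfg <- utils::modifyList(
    list(kernel = "radial", cost_grid = c(0.1, 1, 10), gamma = NULL,
         inner_k = 3L, seed = 1L),
    config)
  x <- as_feature_matrix(features)
  labels <- as.logical(labels)
  stopifnot(nrow(x) == length(labels))
  if (nrow(x) < 2) stop("at least two patients are required")
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class: cannot fit a classifier")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  gamma <- cfg$gamma %||% (1 / ncol(x))
  wts <- c(neg = 0.5 / mean(!labels), pos = 0.5 / mean(labels))
  yf <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))

  cost <- if (length(cfg$cost_grid) == 1) cfg$cost_grid else
    with_seed(cfg$seed, {
      k <- min(cfg$inner_k, min(table(yf)))
      if (k < 2) cfg$cost_grid[ceiling(length(cfg$cost_grid) / 2)] else {
        folds <- stratified_folds(labels, k, derive_seed(cfg$seed, 17L))
        scores <- vapply(cfg$cost_grid, function(cc) {
          aucs <- vapply(seq_len(k), function(f) {
            tr <- folds != f
            if (length(unique(labels[tr])) < 2 ||
                length(unique(labels[!tr])) < 2) return(NA_real_)
            fit <- e1071::svm(xs[tr, , drop = FALSE], yf[tr],
                              kernel = cfg$kernel, cost = cc, gamma = gamma,
                              class.weights = wts, scale = FALSE)
            dv <- attr(stats::predict(fit, xs[!tr, , drop = FALSE],
                                      decision.values = TRUE),
                       "decision.values")[, 1]
            # orient so higher = positive before scoring
            a <- roc_auc(dv, labels[!tr])$auc
            max(a, 1 - a)
          }, numeric(1))
          mean(aucs, na.rm = TRUE)
        }, numeric(1))
        cfg$cost_grid[which.max(scores)]
      }
    })

  fit <- e1071::svm(xs, yf, kernel = cfg$kernel, cost = cost, gamma = gamma,
                    class.weights = wts, scale = FALSE)
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  platt <- fit_platt(dv, labels)
  structure(list(fit = fit, center = center, scale = scale,
                 platt = platt, cost = cost, gamma = gamma,
                 feature_names = colnames(x), seed = cfg$seed,
                 n_train = nrow(x)),
            class = "stenosis_svm")
}

as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features) &&
      all(vapply(features, inherits, logical(1), "patient_features"))) {
    x <- do.call(rbind, lapply(features, as.numeric))
    colnames(x) <- names(features[[1]])
    return(x)
  }
  if (is.data.frame(features)) {
    features <- features[, setdiff(names(features), "patient_id"), drop = FALSE]
    return(as.matrix(features))
  }
  as.matrix(features)
}

# Platt (1999)-style sigmoid calibration: p = 1 / (1 + exp(A f + B)), with
# smoothed targets, fitted by BFGS on the negative log-likelihood.
fit_platt <- function(decision, labels) {
  np <- sum(labels)
  nn <- sum(!labels)
  t_pos <- (np + 1) / (np + 2)
  t_neg <- 1 / (nn + 2)
  tt <- ifelse(labels, t_pos, t_neg)
  nll <- function(ab) {
    z <- ab[1] * decision + ab[2]
    # log(1 + exp(z)) computed stably
    lse <- ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
    sum(tt * lse + (1 - tt) * (lse - z))
  }
  # initialize with the sign that orients larger decision values positive
  init_a <- if (mean(decision[labels]) >= mean(decision[!labels])) -1 else 1
  opt <- stats::optim(c(init_a, 0), nll, method = "BFGS",
                      control = list(maxit = 200))
  list(A = opt$par[1], B = opt$par[2])
}

#' Predict the probability of functionally significant stenosis
#'
#' Applies the stored standardization and the Platt sigmoid to the SVM
#' decision value; the output is a strictly monotone function of the
#' decision value and always lies in `[0, 1]`.
#'
#' @param model a [train_classifier()] model.
#' @param features a feature vector (or matrix of rows) whose length matches
#'   the training features.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "stenosis_svm"))
  if (inherits(features, "patient_features")) features <- as.numeric(features)
  x <- if (is.null(dim(features))) matrix(features, nrow = 1) else
    as_feature_matrix(features)
  if (ncol(x) != length(model$center))
    stop(sprintf("feature length %d does not match the %d training features",
                 ncol(x), length(model$center)))
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  dv <- attr(stats::predict(model$fit, xs, decision.values = TRUE),
             "decision.values")[, 1]
  unname(1 / (1 + exp(model$platt$A * dv + model$platt$B)))
}

#' @export
predict.stenosis_svm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_probability(object, newdata)
  if (type == "prob") p else p > 0.5
}

#' @export
print.stenosis_svm <- function(x, ...) {
  cat(sprintf("<stenosis_svm> RBF SVM on %d features, %d patients (cost %.3g, gamma %.3g)\n",
              length(x$center), x$n_train, x$cost, x$gamma))
  cat(sprintf("  Platt calibration A=%.3f B=%.3f, seed %d\n",
              x$platt$A, x$platt$B, x$seed))
  invisible(x)
}
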