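# ---------------------------------------------------------------------------
# Model-fitting surface: gcnn_fit() and the nested cross-validation driver
# ---------------------------------------------------------------------------

#' Fit a residual graph convolutional network to trait scores
#'
#' The main fitting function. Trains the residual Chebyshev gCNN on
#' per-vertex surface coordinates with the correlation-augmented loss
#' (MSE + l2 penalty - Pearson reward), Adam with stepwise learning-rate
#' decay, optional mesh augmentation, and early stopping on a held-out
#' validation subset with best-weights restoration.
#'
#' @param x a `gcnn_dataset` from [prepare_dataset()], or a padded feature
#'   array `n_padded x f x N` (then `y` and `hierarchy` are required).
#' @param y numeric scores (ignored when `x` is a dataset).
#' @param hierarchy a `graph_hierarchy` (ignored when `x` is a dataset).
#' @param model_config a [gcnn_model_config()].
#' @param train_config a [gcnn_train_config()].
#' @param validation_fraction fraction of subjects held out for early
#'   stopping (seeded split; 0 disables early stopping and trains for
#'   `max_epochs`).
#' @param subset optional integer indices restricting training to a subset
#'   of subjects.
#' @return an object of class `gcnn` with components `model`
#'   (`gcnn_model_state`), `history` (per-epoch losses), `fitted`
#'   (evaluation-mode predictions for all subjects in `x`), `y`,
#'   `train_idx`, `val_idx`, `call`.
#' @seealso [predict.gcnn()], [gcnn_nested_cv()], [gradcam()]
#' @export
gcnn_fit <- function(x, y = NULL, hierarchy = NULL,
                     model_config = NULL,
                     train_config = gcnn_train_config(),
                     validation_fraction = 0.2, subset = NULL) {
  cl <- match.call()
  if (inherits(x, "gcnn_dataset")) {
    dataset <- x
  } else {
    if (is.null(y) || is.null(hierarchy))
      stop("with a raw feature array, y and hierarchy must be supplied")
    if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
    if (dim(x)[3L] != length(y)) stop("y length must match the batch dimension")
    dataset <- structure(list(template = NULL, hierarchy = hierarchy,
                              mode = "combined", padded = x,
                              subject_ids = paste0("s", seq_along(y)),
                              raw_scores = y, scores = y, subjects = NULL),
                         class = "gcnn_dataset")
  }
  n <- length(dataset$scores)
  idx <- if (is.null(subset)) seq_len(n) else as.integer(subset)
  if (is.null(model_config))
    model_config <- gcnn_model_config(
      input_features = dim(dataset$padded)[2L])
  if (validation_fraction > 0) {
    set.seed(train_config$seed)
    n_val <- max(1L, round(validation_fraction * length(idx)))
    val_idx <- sort(sample(idx, n_val))
    train_idx <- setdiff(idx, val_idx)
  } else {
    val_idx <- integer(0)
    train_idx <- idx
  }
  res <- train_gcnn(dataset, train_idx, val_idx, model_config, train_config)
  fitted_vals <- predict_raw(res$model, dataset$padded)
  structure(list(model = res$model, history = res$history,
                 best_epoch = res$best_epoch,
                 fitted = fitted_vals, y = dataset$scores,
                 train_idx = train_idx, val_idx = val_idx,
                 mode = dataset$mode, call = cl),
            class = "gcnn")
}

#' @export
print.gcnn <- function(x, ...) {
  cat("Residual graph convolutional network fit\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  %d subjects (%d train / %d validation), %d epochs run (best %d)\n",
              length(x$y), length(x$train_idx), length(x$val_idx),
              nrow(x$history), x$best_epoch))
  print(x$model)
  invisible(x)
}

#' @export
summary.gcnn <- function(object, ...) {
  tr <- object$train_idx
  m_train <- evaluate_predictions(object$fitted[tr], object$y[tr])
  m_val <- if (length(object$val_idx) >= 3L)
    evaluate_predictions(object$fitted[object$val_idx],
                         object$y[object$val_idx]) else NULL
  out <- list(fit = object, train_metrics = m_train, val_metrics = m_val,
              n_parameters = count_parameters(object$model))
  class(out) <- "summary.gcnn"
  out
}

#' @export
print.summary.gcnn <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Trainable parameters: %d\n", x$n_parameters))
  cat("Training subjects:   ")
  print(x$train_metrics)
  if (!is.null(x$val_metrics)) {
    cat("Validation subjects: ")
    print(x$val_metrics)
  }
  invisible(x)
}

#' Predict trait scores for new subjects
#'
#' @param object a `gcnn` fit.
#' @param newdata padded feature array `n_padded x f x B` (or matrix for one
#'   subject), or a `gcnn_dataset`. Defaults to the fitted values.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.gcnn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(newdata, "gcnn_dataset")) newdata <- newdata$padded
  predict_raw(object$model, newdata)
}

#' @export
fitted.gcnn <- function(object, ...) object$fitted

#' @export
residuals.gcnn <- function(object, ...) object$y - object$fitted

#' @export
coef.gcnn <- function(object, ...) tree_leaves(object$model$params)

#' @export
plot.gcnn <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "predicted score", ylab = "observed score",
       main = "gCNN fit", ...)
  graphics::abline(0, 1, lty = 2)
  if (length(x$val_idx))
    graphics::points(x$fitted[x$val_idx], x$y[x$val_idx], col = 2, pch = 19)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Nested cross-validation with ensembling
# ---------------------------------------------------------------------------

#' Nested cross-validated ensemble evaluation
#'
#' The full evaluation protocol: subjects are split into `outer_k` folds;
#' for each outer fold, the remaining subjects are split into `inner_k`
#' inner folds, one model is trained per inner fold (early-stopped on that
#' inner fold), and the five models' prediction average is evaluated on the
#' never-seen outer test fold.
#'
#' @param dataset a `gcnn_dataset`.
#' @param model_config a [gcnn_model_config()].
#' @param train_config a [gcnn_train_config()].
#' @param outer_k,inner_k fold counts (defaults 6 and 5).
#' @param seed split seed.
#' @param keep_models retain the per-fold member models (needed for
#'   saliency mapping; default `TRUE`).
#' @param verbose print per-fold progress.
#' @return an object of class `gcnn_cv`: `predictions` and `truth` (over
#'   all subjects, each predicted by its outer fold's ensemble),
#'   `fold_metrics` (R, MSE, wall time per fold), `split`, and per-fold
#'   `models`.
#' @export
gcnn_nested_cv <- function(dataset, model_config, train_config,
                           outer_k = 6L, inner_k = 5L, seed = 1L,
                           keep_models = TRUE, verbose = FALSE) {
  stopifnot(inherits(dataset, "gcnn_dataset"))
  ids <- dataset$subject_ids
  split <- make_nested_splits(ids, outer_k = outer_k, inner_k = inner_k,
                              seed = seed)
  preds <- stats::setNames(rep(NA_real_, length(ids)), ids)
  fold_metrics <- data.frame(fold = integer(), r = numeric(),
                             mse = numeric(), seconds = numeric())
  models <- vector("list", outer_k)
  for (of in seq_len(outer_k)) {
    t0 <- proc.time()[["elapsed"]]
    fold <- train_fold(dataset, split, of, model_config, train_config)
    test_idx <- which(split$outer_assignment[ids] == of)
    preds[test_idx] <- ensemble_predict(
      fold$models, dataset$padded[, , test_idx, drop = FALSE])
    met <- evaluate_predictions(preds[test_idx], dataset$scores[test_idx],
                                fold = of)
    el <- proc.time()[["elapsed"]] - t0
    fold_metrics <- rbind(fold_metrics,
                          data.frame(fold = of, r = met$r, mse = met$mse,
                                     seconds = el))
    if (keep_models) models[[of]] <- fold$models
    if (verbose)
      message(sprintf("outer fold %d/%d: R = %.3f, MSE = %.3f (%.1fs)",
                      of, outer_k, met$r, met$mse, el))
  }
  structure(list(predictions = preds, truth = dataset$scores,
                 fold_metrics = fold_metrics, split = split,
                 models = if (keep_models) models else NULL,
                 mode = dataset$mode),
            class = "gcnn_cv")
}

#' @export
print.gcnn_cv <- function(x, ...) {
  cat(sprintf("Nested %d x %d cross-validated gCNN ensemble (%d subjects, mode '%s')\n",
              x$split$outer_k, x$split$inner_k, length(x$predictions), x$mode))
  cat(sprintf("  held-out R = %.4f, MSE = %.4f (pooled over outer folds)\n",
              pearson_guarded(x$predictions, x$truth),
              mean((x$predictions - x$truth)^2)))
  cat(sprintf("  per-fold R: %s\n",
              paste(sprintf("%.3f", x$fold_metrics$r), collapse = ", ")))
  invisible(x)
}

#' @export
summary.gcnn_cv <- function(object, ...) {
  overall <- evaluate_predictions(object$predictions, object$truth)
  out <- list(cv = object, overall = overall)
  class(out) <- "summary.gcnn_cv"
  out
}

#' @export
print.summary.gcnn_cv <- function(x, ...) {
  print(x$cv)
  cat("Pooled held-out metrics: ")
  print(x$overall)
  print(x$cv$fold_metrics, row.names = FALSE)
  invisible(x)
}

#' @export
plot.gcnn_cv <- function(x, ...) {
  plot(x$predictions, x$truth, xlab = "ensemble prediction",
       ylab = "observed score", main = "nested-CV held-out predictions", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Fold-averaged full-resolution saliency maps from a nested-CV run
#'
#' For each outer fold, computes the ensemble Grad-CAM map of every test
#' subject, averages them, and interpolates to full mesh resolution — the
#' per-fold group relevance maps whose mutual spatial correlation measures
#' mapping robustness.
#'
#' @param cv a `gcnn_cv` run with `keep_models = TRUE`.
#' @param dataset the `gcnn_dataset` the run used.
#' @param max_subjects_per_fold cap on test subjects mapped per fold
#'   (`Inf` for all).
#' @return list of level-0 [saliency_map()]s, one per outer fold.
#' @export
fold_saliency_maps <- function(cv, dataset, max_subjects_per_fold = Inf) {
  stopifnot(inherits(cv, "gcnn_cv"), !is.null(cv$models))
  ids <- dataset$subject_ids
  out <- vector("list", cv$split$outer_k)
  for (of in seq_len(cv$split$outer_k)) {
    test_idx <- which(cv$split$outer_assignment[ids] == of)
    if (is.finite(max_subjects_per_fold))
      test_idx <- head(test_idx, max_subjects_per_fold)
    maps <- lapply(test_idx, function(i)
      gradcam_ensemble(cv$models[[of]], dataset$padded[, , i]))
    avg <- average_maps(maps)
    avg$provenance <- sprintf("fold%d", of)
    out[[of]] <- full_resolution_map(avg, dataset$hierarchy)
  }
  out
}
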