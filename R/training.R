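# ---------------------------------------------------------------------------
# Score normalization, augmentation, loss
# ---------------------------------------------------------------------------

#' Gaussian-rank (quantile) normalization of trait scores
#'
#' Monotone mapping of raw scores onto a standard normal. In
#' `deterministic` mode the score of rank `i` (0-based, ties broken by
#' stable input order) maps to the standard-normal quantile at
#' `(i + 0.5) / n`. In `sampled` mode it maps to the i-th order statistic of
#' `n` seeded standard-normal draws — the sorted-random-Gaussian
#' construction used with the cohort data, at the cost of seed-dependent
#' targets. Rank order is preserved either way.
#'
#' @param scores numeric vector (>= 2 finite values).
#' @param mode `"deterministic"` (default) or `"sampled"`.
#' @param seed seed for `sampled` mode.
#' @return numeric vector of normalized scores in input order.
#' @export
quantile_normalize <- function(scores, mode = c("deterministic", "sampled"),
                               seed = 1L) {
  mode <- match.arg(mode)
  if (length(scores) < 2L || any(!is.finite(scores)))
    stop("quantile normalization needs at least 2 finite scores")
  n <- length(scores)
  r <- rank(scores, ties.method = "first")
  if (mode == "deterministic") {
    qnorm((r - 0.5) / n)
  } else {
    set.seed(seed)
    sort(rnorm(n))[r]
  }
}

#' Augment a subject's surface meshes
#'
#' With probability `p_augment` the whole structure set is rotated by three
#' independent angles drawn uniformly within the rotation limit (about the
#' centroid of all vertices, so anatomy-scale geometry is preserved) and
#' i.i.d. Gaussian coordinate noise of standard deviation `noise_sigma` is
#' added. Runs on raw millimetre coordinates, before min-max normalization.
#'
#' @param meshes list of [surface_mesh()] objects (or a `subject_record`).
#' @param config a [gcnn_train_config()] (fields `p_augment`,
#'   `rotation_limit_deg`, `noise_sigma`).
#' @return the (possibly) augmented list of meshes.
#' @export
augment_meshes <- function(meshes, config) {
  rec <- NULL
  if (inherits(meshes, "subject_record")) {
    rec <- meshes
    meshes <- meshes$meshes
  }
  if (runif(1L) < config$p_augment) {
    ang <- runif(3L, -config$rotation_limit_deg, config$rotation_limit_deg) *
      pi / 180
    r <- rot_z(ang[3L]) %*% rot_y(ang[2L]) %*% rot_x(ang[1L])
    all_v <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
    ctr <- colMeans(all_v)
    meshes <- lapply(meshes, function(m) {
      v <- sweep(m$vertices, 2L, ctr)
      v <- sweep(v %*% t(r), 2L, ctr, `+`)
      if (config$noise_sigma > 0)
        v <- v + rnorm(length(v), sd = config$noise_sigma)
      m$vertices <- v
      m
    })
  }
  if (!is.null(rec)) {
    rec$meshes <- meshes
    rec
  } else meshes
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L)

#' Correlation-augmented training loss
#'
#' `L = MSE + lambda1 * reg - lambda2 * corr`: mean squared error between
#' predictions and targets, an l2 penalty on the trainable filter and
#' fully-connected weights (batch-norm parameters and biases excluded), and
#' a Pearson-correlation reward that counteracts regression-to-the-mean
#' shrinkage. `corr` is computed per batch and defined as 0 when either
#' vector has zero variance (including batches of size 1).
#'
#' @param y_p,y_t prediction and target vectors of equal length.
#' @param weights parameter tree of a model (or a plain numeric vector of
#'   regularized weights); `NULL` for no regularization term.
#' @param lambda1,lambda2 loss weights (defaults 1e-4).
#' @return object of class `gcnn_loss`: list with `total`, `mse_term`,
#'   `reg_term`, `corr_term`.
#' @export
compute_loss <- function(y_p, y_t, weights = NULL, lambda1 = 1e-4,
                         lambda2 = 1e-4) {
  if (length(y_p) != length(y_t))
    stop("prediction and target vectors differ in length")
  if (length(y_p) < 1L) stop("empty prediction vector")
  mse <- mean((y_p - y_t)^2)
  reg <- if (is.null(weights)) 0
  else if (is.list(weights)) reg_norm(weights)
  else sum(weights^2)
  corr <- pearson_guarded(y_p, y_t)
  structure(list(total = mse + lambda1 * reg - lambda2 * corr,
                 mse_term = mse, reg_term = reg, corr_term = corr),
            class = "gcnn_loss")
}

## Pearson correlation with a zero-variance (and n = 1) guard.
pearson_guarded <- function(a, b) {
  if (length(a) < 2L) return(0)
  sa <- sd(a); sb <- sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(0)
  cor(a, b)
}

## Gradient of (mse - lambda2 * corr) w.r.t. predictions.
loss_pred_grad <- function(y_p, y_t, lambda2) {
  n <- length(y_p)
  g <- 2 * (y_p - y_t) / n
  if (lambda2 > 0 && n >= 2L) {
    pc <- y_p - mean(y_p)
    tc <- y_t - mean(y_t)
    sp <- sqrt(sum(pc^2)); st <- sqrt(sum(tc^2))
    if (sp > 0 && st > 0) {
      corr <- sum(pc * tc) / (sp * st)
      g <- g - lambda2 * (tc / (sp * st) - corr * pc / sp^2)
    }
  }
  g
}

# ---------------------------------------------------------------------------
# Configuration
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the large-cohort settings: batch size 32, at most 100
#' epochs, Adam with learning rate 5e-4 decayed by 0.99 every 10 optimizer
#' steps, loss weights `lambda1 = lambda2 = 1e-4`, augmentation probability
#' 0.5 (rotations within +-20 degrees, coordinate noise SD 0.02 mm), early
#' stopping patience 5 on inner-validation MSE.
#'
#' @param batch_size,max_epochs,learning_rate,lr_decay,lr_decay_every,lambda1,lambda2,p_augment,rotation_limit_deg,noise_sigma,patience,seed
#'   see Description.
#' @return an object of class `gcnn_train_config`.
#' @export
gcnn_train_config <- function(batch_size = 32L, max_epochs = 100L,
                              learning_rate = 5e-4, lr_decay = 0.99,
                              lr_decay_every = 10L, lambda1 = 1e-4,
                              lambda2 = 1e-4, p_augment = 0.5,
                              rotation_limit_deg = 20, noise_sigma = 0.02,
                              patience = 5L, seed = 1L) {
  stopifnot(batch_size >= 1L, max_epochs >= 1L, learning_rate >= 0,
            lr_decay > 0, lambda1 >= 0, lambda2 >= 0,
            p_augment >= 0, p_augment <= 1, patience >= 1L,
            noise_sigma >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 lambda1 = lambda1, lambda2 = lambda2,
                 p_augment = p_augment,
                 rotation_limit_deg = rotation_limit_deg,
                 noise_sigma = noise_sigma,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "gcnn_train_config")
}

#' Named configuration presets
#'
#' `gcnn_hcp_config()`: the small-cohort variant (batch 50,
#' `lambda1 = 5e-4`, at most 80 epochs). `gcnn_tiny_config()` /
#' `gcnn_tiny_model_config()`: the package's small-study preset used for
#' synthetic-cohort validation — two residual blocks with 8-8-16-16
#' channels, no augmentation, no head dropout, learning rate 1e-3, a
#' correlation weight `lambda2 = 1` (the anti-shrinkage term carries real
#' weight at this scale), at most 18 epochs with patience 6.
#'
#' @param seed integer seed.
#' @return a `gcnn_train_config` (or `gcnn_model_config`).
#' @export
gcnn_hcp_config <- function(seed = 1L) {
  gcnn_train_config(batch_size = 50L, max_epochs = 80L, lambda1 = 5e-4,
                    seed = seed)
}

#' @rdname gcnn_hcp_config
#' @export
gcnn_tiny_config <- function(seed = 1L) {
  gcnn_train_config(batch_size = 32L, max_epochs = 18L, learning_rate = 1e-3,
                    lambda2 = 1, p_augment = 0, patience = 6L, seed = seed)
}

#' @rdname gcnn_hcp_config
#' @export
gcnn_tiny_model_config <- function(seed = 1L) {
  gcnn_model_config(input_features = 9L, channels = c(8L, 8L, 16L, 16L),
                    K = 3L, dropout_rate = 0, seed = seed)
}

# ---------------------------------------------------------------------------
# Nested cross-validation splits
# ---------------------------------------------------------------------------

#' Nested cross-validation fold assignment
#'
#' A seeded uniform shuffle is partitioned into `outer_k` folds as evenly as
#' possible (remainders go to the lowest-indexed folds); within each outer
#' training set the same procedure yields `inner_k` inner folds. Outer folds
#' are disjoint and cover all subjects; inner folds partition the outer
#' training set and never touch the outer test fold.
#'
#' @param subject_ids character vector of unique ids.
#' @param outer_k,inner_k fold counts (defaults 6 and 5).
#' @param seed integer seed.
#' @return an object of class `fold_split`: `outer_assignment` (named fold
#'   index per subject) and `inner_assignment` (per outer fold, named inner
#'   fold index over that fold's training subjects).
#' @export
make_nested_splits <- function(subject_ids, outer_k = 6L, inner_k = 5L,
                               seed = 1L) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (n < outer_k)
    stop(sprintf("%d subjects cannot fill %d outer folds", n, outer_k))
  assign_folds <- function(ids, k, s) {
    set.seed(s)
    shuffled <- sample(ids)
    sizes <- rep(length(ids) %/% k, k)
    rem <- length(ids) %% k
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    f <- rep(seq_len(k), times = sizes)
    stats::setNames(f[match(ids, shuffled)], ids)
  }
  outer <- assign_folds(subject_ids, outer_k, seed)
  inner <- lapply(seq_len(outer_k), function(of) {
    train_ids <- subject_ids[outer != of]
    if (length(train_ids) < inner_k)
      stop("outer training set smaller than the inner fold count")
    assign_folds(train_ids, inner_k, seed + of)
  })
  structure(list(outer_assignment = outer, inner_assignment = inner,
                 outer_k = outer_k, inner_k = inner_k, seed = seed),
            class = "fold_split")
}

# ---------------------------------------------------------------------------
# Training loop
# ---------------------------------------------------------------------------

## Core supervised loop shared by gcnn_fit() and train_fold(): Adam with
## stepwise learning-rate decay, per-batch correlation-augmented loss,
## optional augmentation, early stopping on validation MSE with best-weights
## restoration.
train_gcnn <- function(dataset, train_idx, val_idx, model_config,
                       train_config) {
  stopifnot(inherits(dataset, "gcnn_dataset"))
  if (!length(train_idx)) stop("empty training set")
  model <- build_model(model_config, dataset$hierarchy)
  opt <- adam_init(model$params)
  tc <- train_config
  y <- dataset$scores
  set.seed(tc$seed)
  step <- 0L
  best <- list(val = Inf, params = model$params, bn = model$bn_state,
               epoch = 0L)
  bad <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_mse = numeric(), val_mse = numeric())
  augmenting <- tc$p_augment > 0 && !is.null(dataset$subjects)
  for (epoch in seq_len(tc$max_epochs)) {
    idx <- sample(train_idx)
    ep_loss <- 0; ep_mse <- 0; nb <- 0L
    for (start in seq(1L, length(idx), by = tc$batch_size)) {
      bidx <- idx[start:min(start + tc$batch_size - 1L, length(idx))]
      xb <- dataset$padded[, , bidx, drop = FALSE]
      if (augmenting) {
        for (j in seq_along(bidx)) {
          rec <- augment_meshes(dataset$subjects[[bidx[j]]], tc)
          feat <- encode_features(rec, dataset$template, mode = dataset$mode)
          xb[, , j] <- pad_features(feat, dataset$hierarchy)
        }
      }
      fw <- forward(model, xb, training = TRUE, keep_cache = TRUE)
      model$bn_state <- fw$bn_state
      yb <- y[bidx]
      dpred <- loss_pred_grad(fw$pred, yb, tc$lambda2)
      bw <- backward(model, fw$cache, dpred)
      grads <- add_reg_grad(bw$grads, model$params, tc$lambda1)
      lr <- tc$learning_rate * tc$lr_decay^(step %/% tc$lr_decay_every)
      st <- adam_step(model$params, grads, opt, lr)
      model$params <- st$params
      opt <- st$opt
      step <- step + 1L
      lv <- compute_loss(fw$pred, yb, model$params, tc$lambda1, tc$lambda2)
      ep_loss <- ep_loss + lv$total
      ep_mse <- ep_mse + lv$mse_term
      nb <- nb + 1L
    }
    val_mse <- if (length(val_idx)) {
      vp <- predict_raw(model, dataset$padded[, , val_idx, drop = FALSE])
      mean((vp - y[val_idx])^2)
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         train_mse = ep_mse / nb,
                                         val_mse = val_mse))
    if (length(val_idx)) {
      if (val_mse < best$val) {
        best <- list(val = val_mse, params = model$params,
                     bn = model$bn_state, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= tc$patience) break
      }
    }
  }
  if (length(val_idx)) {
    model$params <- best$params
    model$bn_state <- best$bn
  }
  list(model = model, history = history,
       best_epoch = if (length(val_idx)) best$epoch else nrow(history))
}

## evaluation-mode predictions for a padded feature array, in chunks
predict_raw <- function(model, x, chunk = 64L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  n <- dim(x)[3L]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    out[sel] <- forward(model, x[, , sel, drop = FALSE],
                        training = FALSE)$pred
  }
  out
}

#' Train the five inner-fold models of one outer fold
#'
#' For each inner fold, trains on the remaining four-fifths of the outer
#' training set with the correlation-augmented loss, Adam and early
#' stopping on that inner fold's validation MSE (patience from the training
#' configuration, best weights restored). The five resulting models form
#' the outer fold's ensemble.
#'
#' @param dataset a `gcnn_dataset` (see [prepare_dataset()]).
#' @param split a [make_nested_splits()] result.
#' @param outer_fold outer fold index (its subjects are never seen).
#' @param model_config a [gcnn_model_config()].
#' @param train_config a [gcnn_train_config()].
#' @return list with `models` (5 `gcnn_model_state`s) and `logs` (per-epoch
#'   history per inner fold).
#' @export
train_fold <- function(dataset, split, outer_fold, model_config,
                       train_config) {
  stopifnot(inherits(split, "fold_split"))
  ids <- dataset$subject_ids
  outer <- split$outer_assignment[ids]
  inner <- split$inner_assignment[[outer_fold]]
  models <- vector("list", split$inner_k)
  logs <- vector("list", split$inner_k)
  for (vf in seq_len(split$inner_k)) {
    val_ids <- names(inner)[inner == vf]
    train_ids <- names(inner)[inner != vf]
    if (!length(val_ids) || !length(train_ids))
      stop("empty inner fold in split")
    tc <- train_config
    tc$seed <- train_config$seed + 1000L * outer_fold + vf
    mc <- model_config
    mc$seed <- model_config$seed + 1000L * outer_fold + vf
    res <- train_gcnn(dataset, match(train_ids, ids), match(val_ids, ids),
                      mc, tc)
    models[[vf]] <- res$model
    logs[[vf]] <- res$history
  }
  list(models = models, logs = logs)
}

#' Ensemble predictions by member averaging
#'
#' The outer-fold ensemble prediction for a subject is the arithmetic mean
#' of the member models' evaluation-mode predictions (prediction averaging;
#' weight averaging is ill-defined across batch-norm statistics).
#'
#' @param models list of `gcnn_model_state`s sharing configuration and
#'   template checksum.
#' @param x padded feature array `n_padded x f x B`.
#' @return numeric vector of B ensemble predictions.
#' @export
ensemble_predict <- function(models, x) {
  stopifnot(length(models) >= 1L)
  strip_seed <- function(cfg) { cfg$seed <- NULL; cfg }
  cfg <- strip_seed(models[[1L]]$config)
  chk <- models[[1L]]$checksum
  for (m in models) {
    ## members share the architecture and template; initialization seeds
    ## legitimately differ across inner folds
    if (!identical(strip_seed(m$config), cfg) || !identical(m$checksum, chk))
      stop("ensemble members differ in configuration or template")
  }
  preds <- vapply(models, function(m) predict_raw(m, x),
                  numeric(if (is.matrix(x)) 1L else dim(x)[3L]))
  rowMeans(matrix(preds, ncol = length(models)))
}

# ---------------------------------------------------------------------------
# Metrics and model comparison
# ---------------------------------------------------------------------------

#' Prediction metrics with uncertainty
#'
#' Mean squared error; Pearson R with its Fisher-z 95% confidence interval;
#' and the 95% prediction interval for a new observation from the simple
#' linear regression of targets on predictions (evaluated at the mean
#' prediction).
#'
#' @param y_p,y_t prediction and target vectors (length >= 3).
#' @param fold optional fold label carried through.
#' @return object of class `prediction_metrics`.
#' @export
evaluate_predictions <- function(y_p, y_t, fold = NA) {
  if (length(y_p) != length(y_t)) stop("length mismatch")
  n <- length(y_p)
  if (n < 3L) stop("need at least 3 paired values")
  mse <- mean((y_p - y_t)^2)
  if (sd(y_p) == 0 || sd(y_t) == 0) {
    out <- list(mse = mse, r = NA_real_, r_ci = c(NA_real_, NA_real_),
                pi = c(NA_real_, NA_real_), n = n, fold = fold,
                degenerate = TRUE)
    return(structure(out, class = "prediction_metrics"))
  }
  r <- cor(y_p, y_t)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  r_ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  fit <- lm(y_t ~ y_p, data = data.frame(y_p = y_p, y_t = y_t))
  pi <- predict(fit, newdata = data.frame(y_p = mean(y_p)),
                interval = "prediction", level = 0.95)
  structure(list(mse = mse, r = r, r_ci = r_ci,
                 pi = c(pi[1L, "lwr"], pi[1L, "upr"]), n = n, fold = fold,
                 degenerate = FALSE),
            class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("MSE = %.4f, R = %.4f (95%% CI %.4f-%.4f), n = %d\n",
              x$mse, x$r, x$r_ci[1L], x$r_ci[2L], x$n))
  invisible(x)
}

#' Compare input modes across folds
#'
#' Paired t-tests of per-fold Pearson R between every pair of models
#' (input modes), with Benjamini-Hochberg false-discovery-rate adjustment
#' across all pairs; adjusted p < 0.05 flags a significant difference.
#'
#' @param r_by_model named list (or matrix with folds in rows) of per-fold R
#'   values, equal lengths, folds paired by position.
#' @return data.frame with one row per pair: `model_a`, `model_b`,
#'   `t`, `p`, `p_adj`, `significant`.
#' @export
compare_models <- function(r_by_model) {
  if (is.matrix(r_by_model))
    r_by_model <- as.list(as.data.frame(r_by_model))
  k <- length(r_by_model)
  if (k < 2L) stop("need at least two models to compare")
  lens <- lengths(r_by_model)
  if (length(unique(lens)) != 1L)
    stop("per-fold R vectors must be paired (equal lengths)")
  if (lens[1L] < 2L) stop("need at least 2 paired observations")
  nms <- names(r_by_model)
  if (is.null(nms)) nms <- paste0("model", seq_len(k))
  pairs <- utils::combn(k, 2L)
  res <- data.frame(model_a = nms[pairs[1L, ]], model_b = nms[pairs[2L, ]],
                    t = NA_real_, p = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    a <- r_by_model[[pairs[1L, j]]]
    b <- r_by_model[[pairs[2L, j]]]
    d <- a - b
    if (sd(d) == 0) {
      res$t[j] <- 0
      res$p[j] <- 1
    } else {
      tt <- t.test(a, b, paired = TRUE)
      res$t[j] <- unname(tt$statistic)
      res$p[j] <- tt$p.value
    }
  }
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < 0.05
  res
}
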