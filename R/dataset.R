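# ---------------------------------------------------------------------------
# Prepared datasets: encoded features + hierarchy + normalized scores
# ---------------------------------------------------------------------------

#' Prepare a dataset for training
#'
#' Encodes every subject's node features for the chosen input mode, builds
#' (or reuses) the template's coarsening hierarchy, pads/permutes features
#' onto the hierarchy ordering, and Gaussianizes the raw trait scores by
#' quantile normalization over the full cohort (set
#' `score_scope = "given"` to pass through already-normalized scores, the
#' leakage-safe alternative when normalization is fit on training subjects
#' only).
#'
#' @param subjects list of [subject_record()]s.
#' @param template a `template_graph`.
#' @param mode input mode, see [encode_features()].
#' @param hierarchy optional precomputed `graph_hierarchy`.
#' @param num_levels hierarchy depth when built here (default 4).
#' @param seed coarsening seed.
#' @param score_mode [quantile_normalize()] mode, or `"given"`.
#' @param keep_meshes retain raw meshes (needed for augmentation).
#' @return an object of class `gcnn_dataset`.
#' @export
prepare_dataset <- function(subjects, template,
                            mode = c("combined", "cortical_only",
                                     "subcortical_only"),
                            hierarchy = NULL, num_levels = 4L, seed = 1L,
                            score_mode = "deterministic",
                            keep_meshes = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(subjects) >= 2L)
  if (is.null(hierarchy))
    hierarchy <- coarsen(template, num_levels = num_levels, seed = seed)
  raw <- vapply(subjects, `[[`, 0, "raw_score")
  scores <- if (identical(score_mode, "given")) {
    s <- vapply(subjects, `[[`, 0, "normalized_score")
    if (any(!is.finite(s)))
      stop("score_mode = 'given' needs finite normalized_score on every subject")
    s
  } else quantile_normalize(raw, mode = score_mode, seed = seed)
  n0p <- hierarchy$levels[[1L]]$n_padded
  f <- switch(mode, cortical_only = 6L, subcortical_only = 3L, combined = 9L)
  padded <- array(0, dim = c(n0p, f, length(subjects)))
  for (i in seq_along(subjects)) {
    feat <- encode_features(subjects[[i]], template, mode = mode)
    padded[, , i] <- pad_features(feat, hierarchy)
  }
  structure(list(template = template, hierarchy = hierarchy, mode = mode,
                 padded = padded,
                 subject_ids = vapply(subjects, `[[`, "", "subject_id"),
                 raw_scores = raw, scores = scores,
                 subjects = if (keep_meshes) subjects else NULL),
            class = "gcnn_dataset")
}

#' @export
print.gcnn_dataset <- function(x, ...) {
  cat(sprintf("gcnn_dataset: %d subjects, mode '%s', %d graph vertices (%d padded), %d hierarchy levels\n",
              length(x$subject_ids), x$mode, x$template$n,
              dim(x$padded)[1L], x$hierarchy$num_levels))
  invisible(x)
}

#' Persist a prepared dataset
#'
#' Single-file native R serialization of the full `gcnn_dataset` container
#' (template, hierarchy, features, scores).
#'
#' @param dataset a `gcnn_dataset`.
#' @param path file path.
#' @return `path` invisibly / the restored `gcnn_dataset`.
#' @export
write_gcnn_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "gcnn_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_gcnn_dataset
#' @export
read_gcnn_dataset <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "gcnn_dataset")) stop("not a gcnn_dataset file")
  obj
}
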