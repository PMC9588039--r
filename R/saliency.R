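# ---------------------------------------------------------------------------
# Graph Grad-CAM saliency
# ---------------------------------------------------------------------------

#' Saliency map container
#'
#' Nonnegative per-vertex relevance values, at a coarse hierarchy level or
#' at full template resolution (level 0, original vertex order).
#'
#' @param values nonnegative numeric vector.
#' @param level 0-based hierarchy level the values live on.
#' @param mode input mode provenance (`"combined"`, `"cortical_only"`,
#'   `"subcortical_only"`).
#' @param checksum template checksum the map belongs to.
#' @param provenance free-form subject/fold tag.
#' @return an object of class `saliency_map`.
#' @export
saliency_map <- function(values, level, mode = "combined", checksum = NULL,
                         provenance = NULL) {
  values <- as.numeric(values)
  if (any(values < -1e-12)) stop("saliency values must be nonnegative")
  structure(list(values = pmax(values, 0), level = level, mode = mode,
                 checksum = checksum, provenance = provenance),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency_map: level %d, %d vertices, max %.4g\n",
              x$level, length(x$values), max(x$values)))
  invisible(x)
}

#' Grad-CAM relevance map for one subject
#'
#' Gradient-weighted class activation mapping on the last convolutional
#' layer (the post residual block's final convolution, at the coarsest
#' hierarchy level): channel importance weights are the node-averaged
#' gradients of the prediction with respect to that layer's activations,
#' `alpha_k = (1/N) sum_n d y / d A_{nk}`, and the map is
#' `M = ReLU(sum_k alpha_k A_k)` — only positively contributing features are
#' kept. Evaluation-mode, deterministic.
#'
#' @param model a `gcnn_model_state` (or `gcnn` fit).
#' @param x one subject's padded feature matrix (`n_padded x f`), e.g. a
#'   slice of `dataset$padded`.
#' @return a [saliency_map()] at the coarsest model level (real vertices
#'   only).
#' @export
gradcam <- function(model, x) {
  if (inherits(model, "gcnn")) model <- model$model
  stopifnot(inherits(model, "gcnn_model_state"))
  fw <- forward(model, x, training = FALSE, keep_cache = TRUE)
  bw <- backward(model, fw$cache, dpred = 1, want_alast_grad = TRUE)
  a <- fw$cache$a_last          # channels x vertices (single subject)
  da <- bw$da_last
  nb <- model$config$n_blocks
  lev <- model$hierarchy$levels[[nb + 1L]]
  real <- !lev$fake_mask
  alpha <- rowMeans(da[, real, drop = FALSE])     # 1/N node-averaged gradients
  m <- pmax(as.numeric(crossprod(a[, real, drop = FALSE], alpha)), 0)
  saliency_map(m, level = nb, checksum = model$checksum)
}

#' Grad-CAM map of a model ensemble
#'
#' Averages the member models' coarse Grad-CAM maps, consistent with
#' prediction averaging.
#'
#' @param models list of `gcnn_model_state`s.
#' @param x one subject's padded feature matrix.
#' @return a [saliency_map()] at the coarsest model level.
#' @export
gradcam_ensemble <- function(models, x) {
  maps <- lapply(models, gradcam, x = x)
  average_maps(maps)
}

#' Interpolate a saliency map to full mesh resolution
#'
#' Delegates to [upsample_map()]: parent-copy down the hierarchy followed by
#' inverse-distance 1-ring smoothing. Nonnegativity is preserved (convex
#' combinations).
#'
#' @param coarse a [saliency_map()] at a coarse level.
#' @param hierarchy the `graph_hierarchy` the model was built on.
#' @return a [saliency_map()] at level 0 (template vertex order).
#' @export
full_resolution_map <- function(coarse, hierarchy) {
  stopifnot(inherits(coarse, "saliency_map"),
            inherits(hierarchy, "graph_hierarchy"))
  if (!is.null(coarse$checksum) &&
      !identical(coarse$checksum, hierarchy$checksum))
    stop("template checksum mismatch between map and hierarchy")
  v <- upsample_map(coarse$values, hierarchy, from_level = coarse$level)
  saliency_map(v, level = 0L, mode = coarse$mode, checksum = coarse$checksum,
               provenance = coarse$provenance)
}

#' Average a collection of saliency maps
#'
#' Elementwise arithmetic mean; all maps must live on the same vertex set.
#'
#' @param maps non-empty list of [saliency_map()]s of equal length and mode.
#' @return a [saliency_map()].
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stop("cannot average an empty collection of maps")
  len <- length(maps[[1L]]$values)
  for (m in maps) {
    stopifnot(inherits(m, "saliency_map"))
    if (length(m$values) != len || !identical(m$mode, maps[[1L]]$mode))
      stop("maps differ in length or mode")
  }
  vals <- rowMeans(vapply(maps, `[[`, numeric(len), "values"))
  saliency_map(vals, level = maps[[1L]]$level, mode = maps[[1L]]$mode,
               checksum = maps[[1L]]$checksum)
}

#' Spatial correlation between two saliency maps
#'
#' Pearson correlation across the selected vertices; the robustness
#' statistic for comparing maps from different folds, cohorts or input
#' modes. Pearson correlation is affine-invariant, so any display scaling
#' of the maps does not matter.
#'
#' @param map1,map2 full-resolution [saliency_map()]s on the same template.
#' @param template the `template_graph` (needed for `scope` other than
#'   `"all"`).
#' @param scope `"all"`, `"cortical"` or `"subcortical"` vertex subset.
#' @return Pearson correlation; `NA` (with a warning) if either map has
#'   zero variance over the scope.
#' @export
spatial_correlation <- function(map1, map2, template = NULL,
                                scope = c("all", "cortical", "subcortical")) {
  scope <- match.arg(scope)
  v1 <- if (inherits(map1, "saliency_map")) map1$values else as.numeric(map1)
  v2 <- if (inherits(map2, "saliency_map")) map2$values else as.numeric(map2)
  if (length(v1) != length(v2)) stop("maps live on different vertex sets")
  if (scope != "all") {
    if (is.null(template)) stop("scoped correlation needs the template graph")
    cortical <- template$partition$structure == "cortex"
    sel <- if (scope == "cortical") cortical else !cortical
    v1 <- v1[sel]; v2 <- v2[sel]
  }
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("zero variance over the requested scope; correlation undefined")
    return(NA_real_)
  }
  cor(v1, v2)
}

#' Write a full-resolution saliency map as per-vertex CSV
#'
#' One row per template vertex: index, structure, hemisphere, value.
#'
#' @param map a level-0 [saliency_map()].
#' @param template the `template_graph`.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_saliency_csv <- function(map, template, path) {
  stopifnot(inherits(map, "saliency_map"), map$level == 0L)
  d <- data.frame(vertex = seq_len(template$n),
                  structure = template$partition$structure,
                  hemisphere = template$partition$hemisphere,
                  value = map$values)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
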