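# ---------------------------------------------------------------------------
# Graph Laplacians
# ---------------------------------------------------------------------------

#' Build a graph Laplacian
#'
#' Combinatorial form `L = D - A` or symmetric-normalized form
#' `L = I - D^{-1/2} A D^{-1/2}`. Zero-degree vertices (including padding
#' vertices in a coarsening hierarchy) get all-zero rows/columns in the
#' normalized form, i.e. eigenvalue 0.
#'
#' @param graph a `template_graph` or a symmetric nonnegative sparse
#'   adjacency matrix.
#' @param kind `"normalized"` (default) or `"combinatorial"`.
#' @param lambda_max `"power"` (default; power iteration to relative
#'   tolerance 1e-6, capped at 2 for normalized Laplacians) or `"fixed"`
#'   (use 2, the normalized upper bound).
#' @return an object of class `graph_laplacian` with fields `matrix`, `kind`,
#'   `degree` and `lambda_max`. Edgeless graphs carry the `lambda_max = 2`
#'   convention so that scaling maps them to `-I`.
#' @export
build_laplacian <- function(graph, kind = c("normalized", "combinatorial"),
                            lambda_max = c("power", "fixed")) {
  kind <- match.arg(kind)
  lambda_max <- match.arg(lambda_max)
  a <- if (inherits(graph, "template_graph")) graph$adjacency else graph
  a <- as(a, "CsparseMatrix")
  if (!isTRUE(Matrix::isSymmetric(a, tol = 0)))
    stop("adjacency matrix must be symmetric")
  if (length(a@x) && min(a@x) < 0)
    stop("adjacency matrix must be nonnegative")
  n <- nrow(a)
  deg <- Matrix::rowSums(a)
  if (kind == "combinatorial") {
    l <- Matrix::Diagonal(n, deg) - a
  } else {
    dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    l <- Matrix::Diagonal(n, dinv) %*% a %*% Matrix::Diagonal(n, dinv)
    l <- Matrix::Diagonal(n, as.numeric(deg > 0)) - l
  }
  l <- as(Matrix::forceSymmetric(l), "generalMatrix")
  lmax <- if (all(deg == 0)) 2 else if (lambda_max == "fixed" &&
                                        kind == "normalized") 2
  else {
    ## power iteration converges to lambda_max from below; inflate by a
    ## hair so the scaled spectrum is certain to stay inside [-1, 1]
    est <- power_lambda_max(l) * (1 + 1e-3)
    if (kind == "normalized") min(est, 2) else est
  }
  structure(list(matrix = as(l, "CsparseMatrix"), kind = kind,
                 degree = deg, lambda_max = lmax),
            class = "graph_laplacian")
}

## Largest eigenvalue of a symmetric PSD sparse matrix by power iteration.
power_lambda_max <- function(l, tol = 1e-9, maxit = 2000L) {
  n <- nrow(l)
  if (n == 0L) return(0)
  ## deterministic, generic start vector (not orthogonal to the top
  ## eigenvector for any graph arising here)
  x <- sin(seq_len(n)) + 0.5
  x <- x / sqrt(sum(x^2))
  lam <- 0
  for (it in seq_len(maxit)) {
    y <- as.numeric(l %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    lam_new <- sum(x * y)
    x <- y / ny
    if (it > 100L && abs(lam_new - lam) <= tol * abs(lam_new)) {
      lam <- lam_new
      break
    }
    lam <- lam_new
  }
  ## one Rayleigh step for a slightly sharper estimate
  max(lam, sum(x * as.numeric(l %*% x)))
}

#' @export
print.graph_laplacian <- function(x, ...) {
  cat(sprintf("graph_laplacian (%s): %d vertices, lambda_max = %.6f\n",
              x$kind, nrow(x$matrix), x$lambda_max))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Coarsening hierarchy (heavy-edge matching, Graclus style)
# ---------------------------------------------------------------------------

## One level of heavy-edge matching. Returns a cluster id per vertex
## (1..n_clusters). Visiting order is a seeded shuffle; each unmatched vertex
## grabs the unmatched neighbour maximizing w_ij * (1/d_i + 1/d_j)
## (normalized-cut flavoured heavy-edge weight); vertices left over become
## singleton clusters.
match_level <- function(a, seed) {
  n <- nrow(a)
  deg <- Matrix::rowSums(a)
  set.seed(seed)
  order <- sample.int(n)
  cluster <- integer(n)
  nc <- 0L
  ap <- as(a, "CsparseMatrix")
  for (v in order) {
    if (cluster[v] > 0L) next
    nc <- nc + 1L
    cluster[v] <- nc
    ptr <- (ap@p[v] + 1L):ap@p[v + 1L]
    if (ap@p[v + 1L] > ap@p[v]) {
      nb <- ap@i[ptr] + 1L
      w <- ap@x[ptr]
      free <- cluster[nb] == 0L
      if (any(free)) {
        nb <- nb[free]; w <- w[free]
        score <- w * (1 / max(deg[v], .Machine$double.eps) +
                        1 / pmax(deg[nb], .Machine$double.eps))
        best <- nb[order(-score, nb)][1L]
        cluster[best] <- nc
      }
    }
  }
  cluster
}

#' Build a multilevel coarsening hierarchy
#'
#' Repeated heavy-edge matching merges vertex pairs so that each level has
#' exactly half as many (padded) vertices as the one below: unmatched
#' vertices are paired with inserted "fake" vertices that carry no edges, and
#' vertices are reordered so that the two children of every parent are
#' adjacent in memory (stride-2 pooling becomes a reduction over consecutive
#' row pairs). Coarse edge weights are the summed inter-cluster weights.
#' The result is deterministic given `seed` and is computed once per
#' template, then shared by every subject.
#'
#' @param graph a `template_graph`.
#' @param num_levels number of coarsening levels (>= 0).
#' @param seed integer seed for the matching order.
#' @param kind Laplacian kind for every level, see [build_laplacian()].
#' @param lambda_max passed to [build_laplacian()].
#' @return an object of class `graph_hierarchy`; level `l` (0-based) holds
#'   `adjacency`, `laplacian`, `scaled` (scaled Laplacian matrix),
#'   `n_padded`, `n_real` and `fake_mask`. `perm0` maps level-0 padded slots
#'   to original template vertices (NA for padding); `interp` is the sparse
#'   row-stochastic 1-ring interpolation operator used by [upsample_map()].
#' @export
coarsen <- function(graph, num_levels, seed = 1L,
                    kind = c("normalized", "combinatorial"),
                    lambda_max = c("power", "fixed")) {
  stopifnot(inherits(graph, "template_graph"), num_levels >= 0L)
  kind <- match.arg(kind)
  lambda_max <- match.arg(lambda_max)
  adj <- list(graph$adjacency)           # real (unpadded) adjacency per level
  clusters <- list()
  for (l in seq_len(num_levels)) {
    cl <- match_level(adj[[l]], seed = seed + l)
    m <- max(cl)
    s <- Matrix::sparseMatrix(i = seq_along(cl), j = cl, x = 1,
                              dims = c(length(cl), m))
    ac <- Matrix::crossprod(s, adj[[l]] %*% s)
    Matrix::diag(ac) <- 0
    ac <- Matrix::drop0(ac)
    adj[[l + 1L]] <- as(ac, "CsparseMatrix")
    clusters[[l]] <- cl
  }
  n_real <- vapply(adj, nrow, 0L)
  ## sibling-contiguous permutation, built from the coarsest level down;
  ## perm[[l]] lists, per padded slot, the real vertex id at level l (or NA).
  perm <- vector("list", num_levels + 1L)
  perm[[num_levels + 1L]] <- seq_len(n_real[num_levels + 1L])
  if (num_levels > 0L) {
    for (l in num_levels:1L) {
      cl <- clusters[[l]]
      ch <- split(seq_along(cl), cl)        # children per real parent
      out <- integer(0)
      for (p in perm[[l + 1L]]) {
        kids <- if (!is.na(p)) ch[[as.character(p)]] else integer(0)
        if (length(kids) > 2L)
          stop("internal error: more than two children in matching")
        kids <- c(kids, rep(NA_integer_, 2L - length(kids)))
        out <- c(out, kids)
      }
      perm[[l]] <- out
    }
  }
  levels <- vector("list", num_levels + 1L)
  for (l in seq_len(num_levels + 1L)) {
    p <- perm[[l]]
    np <- length(p)
    fake <- is.na(p)
    ## padded, permuted adjacency: position i <- real vertex p[i]
    a <- adj[[l]]
    pos <- integer(n_real[l]); pos[p[!fake]] <- which(!fake)
    ac <- as(a, "TsparseMatrix")
    ap <- Matrix::sparseMatrix(i = pos[ac@i + 1L], j = pos[ac@j + 1L],
                               x = ac@x, dims = c(np, np))
    lap <- build_laplacian(ap, kind = kind, lambda_max = lambda_max)
    levels[[l]] <- list(adjacency = as(ap, "CsparseMatrix"),
                        laplacian = lap,
                        scaled = scale_laplacian(lap)$matrix,
                        n_padded = np, n_real = n_real[l],
                        fake_mask = fake, perm = p)
  }
  structure(list(levels = levels, num_levels = num_levels,
                 perm0 = perm[[1L]], template_n = graph$n,
                 interp = interp_operator(graph), seed = seed,
                 checksum = template_checksum(graph)),
            class = "graph_hierarchy")
}

#' @export
print.graph_hierarchy <- function(x, ...) {
  cat(sprintf("graph_hierarchy: %d levels\n", x$num_levels))
  for (l in seq_along(x$levels))
    cat(sprintf("  level %d: %d padded (%d real) vertices\n", l - 1L,
                x$levels[[l]]$n_padded, x$levels[[l]]$n_real))
  invisible(x)
}

## Cheap structural checksum tying models/saliency to their template.
template_checksum <- function(graph) {
  paste(graph$n, length(graph$adjacency@x),
        format(sum(graph$adjacency@x), digits = 15L),
        format(sum(graph$coordinates * graph$coordinates), digits = 15L),
        sep = "/")
}

## Row-stochastic 1-ring smoothing operator on the full template: neighbour
## weights are inverse Euclidean edge lengths (geodesic on the template's
## sphere parameterization up to first order), the self weight equals the
## neighbour total, rows normalized to sum 1.
interp_operator <- function(graph) {
  a <- as(graph$adjacency, "TsparseMatrix")
  n <- graph$n
  if (!length(a@x))
    return(Matrix::Diagonal(n))
  i <- a@i + 1L; j <- a@j + 1L
  d <- sqrt(rowSums((graph$coordinates[i, , drop = FALSE] -
                       graph$coordinates[j, , drop = FALSE])^2))
  w <- 1 / pmax(d, .Machine$double.eps)
  nbr_tot <- as.numeric(Matrix::sparseMatrix(i = i, j = rep(1L, length(i)),
                                             x = w, dims = c(n, 1L)))
  ii <- c(i, seq_len(n)); jj <- c(j, seq_len(n))
  ww <- c(w, ifelse(nbr_tot > 0, nbr_tot, 1))
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  rs <- Matrix::rowSums(m)
  as(Matrix::Diagonal(n, 1 / rs) %*% m, "CsparseMatrix")
}

# ---------------------------------------------------------------------------
# Pooling and upsampling
# ---------------------------------------------------------------------------

#' Max-pool node features one level down the hierarchy
#'
#' Each coarse vertex takes the elementwise maximum over its two children;
#' fake (padding) children are neutral and never win. Pairs whose children
#' are both fake yield 0.
#'
#' @param values numeric matrix with one row per padded vertex of `level`.
#' @param hierarchy a `graph_hierarchy`.
#' @param level 0-based level the values live on (pooled to `level + 1`).
#' @return matrix with `n_padded(level + 1)` rows.
#' @export
pool_features <- function(values, hierarchy, level = 0L) {
  stopifnot(inherits(hierarchy, "graph_hierarchy"))
  if (level < 0L || level >= hierarchy$num_levels)
    stop("level out of range for this hierarchy")
  lev <- hierarchy$levels[[level + 1L]]
  values <- as.matrix(values)
  if (nrow(values) != lev$n_padded)
    stop(sprintf("values have %d rows; level %d has %d padded vertices",
                 nrow(values), level, lev$n_padded))
  np <- lev$n_padded
  odd <- seq(1L, np, by = 2L); even <- seq(2L, np, by = 2L)
  a <- values[odd, , drop = FALSE]
  b <- values[even, , drop = FALSE]
  a[lev$fake_mask[odd], ] <- -Inf
  b[lev$fake_mask[even], ] <- -Inf
  out <- pmax(a, b)
  out[!is.finite(out)] <- 0
  out
}

#' Interpolate a coarse per-vertex map back to full resolution
#'
#' Values are propagated down the hierarchy by assigning every child its
#' parent's value, then smoothed by one pass of the precomputed
#' inverse-distance 1-ring interpolation operator (a convex combination, so
#' the value range is preserved). Output is in original template vertex
#' order.
#'
#' @param coarse_values numeric vector at level `from_level`: either the
#'   padded length or the real (non-fake) vertex count of that level.
#' @param hierarchy a `graph_hierarchy`.
#' @param from_level 0-based level the values live on.
#' @param smooth apply the interpolation smoothing pass (default `TRUE`).
#' @return numeric vector of length `hierarchy$template_n`.
#' @export
upsample_map <- function(coarse_values, hierarchy, from_level = NULL,
                         smooth = TRUE) {
  stopifnot(inherits(hierarchy, "graph_hierarchy"))
  if (is.null(from_level)) from_level <- hierarchy$num_levels
  if (from_level < 0L || from_level > hierarchy$num_levels)
    stop("from_level out of range for this hierarchy")
  lev <- hierarchy$levels[[from_level + 1L]]
  v <- as.numeric(coarse_values)
  if (length(v) == lev$n_real && lev$n_real != lev$n_padded) {
    full <- numeric(lev$n_padded)
    full[!lev$fake_mask] <- v
    v <- full
  } else if (length(v) != lev$n_padded) {
    stop(sprintf("coarse_values length %d matches neither padded (%d) nor real (%d) count of level %d",
                 length(v), lev$n_padded, lev$n_real, from_level))
  }
  l <- from_level
  while (l > 0L) {
    v <- rep(v, each = 2L)               # children inherit the parent value
    l <- l - 1L
  }
  lev0 <- hierarchy$levels[[1L]]
  out <- numeric(hierarchy$template_n)
  out[lev0$perm[!lev0$fake_mask]] <- v[!lev0$fake_mask]
  if (smooth) out <- as.numeric(hierarchy$interp %*% out)
  out
}
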