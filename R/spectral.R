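# ---------------------------------------------------------------------------
# Scaled Laplacian and Chebyshev spectral filtering
# ---------------------------------------------------------------------------

#' Scale a Laplacian to the Chebyshev-stable interval
#'
#' Computes `Lt = 2 L / lambda_max - I`, mapping the spectrum into
#' \[-1, 1\] where Chebyshev polynomials of the first kind are stable.
#' Edgeless graphs use the `lambda_max = 2` convention, giving `Lt = -I`.
#'
#' @param lap a `graph_laplacian` from [build_laplacian()].
#' @return an object of class `scaled_laplacian` with fields `matrix`,
#'   `kind` and `lambda_max`.
#' @export
scale_laplacian <- function(lap) {
  stopifnot(inherits(lap, "graph_laplacian"))
  if (!is.finite(lap$lambda_max) || lap$lambda_max <= 0)
    stop("lambda_max must be positive to scale a Laplacian")
  n <- nrow(lap$matrix)
  m <- (2 / lap$lambda_max) * lap$matrix - Matrix::Diagonal(n)
  structure(list(matrix = as(m, "CsparseMatrix"), kind = lap$kind,
                 lambda_max = lap$lambda_max),
            class = "scaled_laplacian")
}

#' Chebyshev filter specification
#'
#' A K-localized spectral filter: coefficients `theta[f_in, f_out, k]`
#' weight the Chebyshev polynomial `T_{k-1}` of the scaled Laplacian for
#' each (input feature, output feature) pair. The trainable parameter count
#' is `F_in * F_out * K`; the optional per-output bias is standard in this
#' architecture family and excluded from that count.
#'
#' @param theta numeric array of dimension `c(F_in, F_out, K)` (a matrix is
#'   accepted for `K = 1`).
#' @param bias optional numeric vector of length `F_out`.
#' @return an object of class `cheb_filter_spec`.
#' @export
cheb_filter_spec <- function(theta, bias = NULL) {
  if (is.matrix(theta)) theta <- array(theta, dim = c(dim(theta), 1L))
  stopifnot(is.array(theta), length(dim(theta)) == 3L)
  if (any(!is.finite(theta))) stop("filter coefficients must be finite")
  if (!is.null(bias) && length(bias) != dim(theta)[2L])
    stop("bias length must equal F_out")
  structure(list(theta = theta, bias = bias,
                 K = dim(theta)[3L],
                 F_in = dim(theta)[1L], F_out = dim(theta)[2L]),
            class = "cheb_filter_spec")
}

## Stacked Chebyshev basis [T_0(Lt) X | T_1(Lt) X | ... | T_{K-1}(Lt) X]
## computed by the three-term recurrence T_k = 2 Lt T_{k-1} - T_{k-2}
## on sparse matrix products; T_k(Lt) itself is never materialized.
cheb_basis <- function(lt, x, k) {
  f <- ncol(x)
  out <- matrix(0, nrow(x), k * f)
  out[, seq_len(f)] <- x
  if (k >= 2L) {
    t_prev <- x
    t_cur <- as.matrix(lt %*% x)
    out[, f + seq_len(f)] <- t_cur
    if (k >= 3L) for (j in 3:k) {
      t_new <- 2 * as.matrix(lt %*% t_cur) - t_prev
      out[, (j - 1L) * f + seq_len(f)] <- t_new
      t_prev <- t_cur
      t_cur <- t_new
    }
  }
  out
}

#' Apply a K-localized Chebyshev spectral filter
#'
#' Computes `y = sum_k T_k(Lt) x theta_k (+ bias)` with `T_0 = I`,
#' `T_1 = Lt` and the three-term recurrence, using only sparse
#' matrix-vector products.
#'
#' @param x numeric matrix `n x F_in` of node features.
#' @param scaled a `scaled_laplacian` (or a `graph_laplacian`, scaled on the
#'   fly).
#' @param spec a [cheb_filter_spec()].
#' @return numeric matrix `n x F_out`.
#' @export
cheb_filter <- function(x, scaled, spec) {
  if (inherits(scaled, "graph_laplacian")) scaled <- scale_laplacian(scaled)
  stopifnot(inherits(scaled, "scaled_laplacian"),
            inherits(spec, "cheb_filter_spec"))
  x <- as.matrix(x)
  if (ncol(x) != spec$F_in)
    stop(sprintf("x has %d features but the filter expects F_in = %d",
                 ncol(x), spec$F_in))
  if (nrow(x) != nrow(scaled$matrix))
    stop("x row count does not match the Laplacian dimension")
  basis <- cheb_basis(scaled$matrix, x, spec$K)
  y <- basis %*% theta_stack_cached(spec)
  if (!is.null(spec$bias)) y <- sweep(y, 2L, spec$bias, `+`)
  y
}

theta_stack_cached <- function(spec) {
  k <- spec$K
  m <- matrix(0, k * spec$F_in, spec$F_out)
  for (j in seq_len(k))
    m[(j - 1L) * spec$F_in + seq_len(spec$F_in), ] <- spec$theta[, , j]
  m
}

#' Dense spectral-decomposition filtering oracle
#'
#' Test-only reference path: eigendecomposes `L = U Lambda U'`, evaluates the
#' scalar Chebyshev polynomial filter on the scaled eigenvalues and returns
#' `U g(Lambda) U' x` per feature pair. Equals [cheb_filter()] up to
#' numerical error; refuses graphs above `max_n` vertices.
#'
#' @param x numeric matrix `n x F_in`.
#' @param lap a `graph_laplacian`.
#' @param spec a [cheb_filter_spec()] (bias applied identically).
#' @param max_n refusal bound for the dense path (default 200).
#' @return list with `y` (`n x F_out`), `transform` (function computing
#'   `U' x`) and `inverse` (function computing `U xt`).
#' @export
spectral_oracle <- function(x, lap, spec, max_n = 200L) {
  stopifnot(inherits(lap, "graph_laplacian"),
            inherits(spec, "cheb_filter_spec"))
  n <- nrow(lap$matrix)
  if (n > max_n)
    stop(sprintf("spectral_oracle is a dense test-only path (n = %d > %d)",
                 n, max_n))
  x <- as.matrix(x)
  eig <- eigen(as.matrix(lap$matrix), symmetric = TRUE)
  u <- eig$vectors
  lam_scaled <- 2 * eig$values / lap$lambda_max - 1
  ## scalar Chebyshev polynomials of the scaled eigenvalues
  tk <- matrix(0, n, spec$K)
  tk[, 1L] <- 1
  if (spec$K >= 2L) tk[, 2L] <- lam_scaled
  if (spec$K >= 3L) for (j in 3:spec$K)
    tk[, j] <- 2 * lam_scaled * tk[, j - 1L] - tk[, j - 2L]
  xt <- crossprod(u, x)                          # forward transform U' x
  y <- matrix(0, n, spec$F_out)
  for (g in seq_len(spec$F_out)) {
    acc <- numeric(n)
    for (f in seq_len(spec$F_in)) {
      gl <- as.numeric(tk %*% spec$theta[f, g, ]) # g_theta at each eigenvalue
      acc <- acc + gl * xt[, f]
    }
    y[, g] <- u %*% acc
  }
  if (!is.null(spec$bias)) y <- sweep(y, 2L, spec$bias, `+`)
  list(y = y,
       transform = function(z) crossprod(u, as.matrix(z)),
       inverse = function(zt) u %*% as.matrix(zt))
}
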