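test_that("normalized Laplacian of a single edge is [[1,-1],[-1,1]]", {
  a <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1)
  lap <- build_laplacian(a, "normalized")
  expect_equal(as.matrix(lap$matrix), matrix(c(1, -1, -1, 1), 2L),
               ignore_attr = TRUE)
  ev <- eigen(as.matrix(lap$matrix), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, 2), tolerance = 1e-12)
  expect_equal(lap$lambda_max, 2, tolerance = 1e-5)
})

test_that("combinatorial Laplacian rows sum to zero; edgeless graph gives 0", {
  for (s in 1:5) {
    lap <- build_laplacian(rand_adjacency(15L, seed = s), "combinatorial")
    expect_lt(max(abs(Matrix::rowSums(lap$matrix))), 1e-12)
  }
  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(4, 4))
  lap0 <- build_laplacian(empty, "combinatorial")
  expect_equal(max(abs(lap0$matrix)), 0)
})

test_that("asymmetric adjacency is rejected", {
  bad <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3))
  expect_error(build_laplacian(bad), "symmetric")
})

test_that("scaled Laplacian maps the single-edge case to [[0,-1],[-1,0]] and an edgeless graph to -I", {
  a <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1)
  sc <- scale_laplacian(build_laplacian(a, "normalized", lambda_max = "fixed"))
  expect_equal(as.matrix(sc$matrix), matrix(c(0, -1, -1, 0), 2L),
               ignore_attr = TRUE)
  empty <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(3, 3))
  sc0 <- scale_laplacian(build_laplacian(empty, "combinatorial"))
  expect_equal(as.matrix(sc0$matrix), -diag(3), ignore_attr = TRUE)
})

test_that("scaled-Laplacian eigenvalues lie in [-1, 1] on random graphs", {
  for (s in 1:10) {
    lap <- build_laplacian(rand_adjacency(20L, seed = s), "normalized")
    sc <- scale_laplacian(lap)
    ev <- eigen(as.matrix(sc$matrix), symmetric = TRUE, only.values = TRUE)$values
    expect_lt(max(abs(ev)), 1 + 1e-8)
  }
})

test_that("K=1 filtering with identity coefficients reproduces the input", {
  sc <- scaled_from_matrix(rand_adjacency(12L, seed = 2))
  x <- matrix(rnorm(12 * 2), 12L, 2L)
  spec <- cheb_filter_spec(array(diag(2), dim = c(2, 2, 1)))
  expect_equal(cheb_filter(x, sc, spec), x, ignore_attr = TRUE)
})

test_that("K=2 with theta = (0, 1) applies the scaled Laplacian once", {
  sc <- scaled_from_matrix(rand_adjacency(12L, seed = 4))
  x <- matrix(rnorm(12), 12L, 1L)
  theta <- array(0, dim = c(1, 1, 2))
  theta[1, 1, 2] <- 1
  y <- cheb_filter(x, sc, cheb_filter_spec(theta))
  expect_equal(y, as.matrix(sc$matrix %*% x), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("Chebyshev recurrence agrees with the dense spectral oracle", {
  set.seed(99)
  for (trial in 1:20) {
    n <- sample(8:40, 1)
    k <- sample(1:5, 1)
    fi <- sample(1:3, 1); fo <- sample(1:3, 1)
    lap <- build_laplacian(rand_adjacency(n, seed = 100 + trial), "normalized")
    spec <- cheb_filter_spec(array(rnorm(fi * fo * k), c(fi, fo, k)),
                             bias = rnorm(fo))
    x <- matrix(rnorm(n * fi), n, fi)
    y1 <- cheb_filter(x, scale_laplacian(lap), spec)
    y2 <- spectral_oracle(x, lap, spec)$y
    expect_lt(max(abs(y1 - y2)), 1e-8)
  }
})

test_that("an eigenvector of L is a fixed direction of the spectral filter", {
  lap <- build_laplacian(rand_adjacency(15L, seed = 7), "normalized")
  eig <- eigen(as.matrix(lap$matrix), symmetric = TRUE)
  u <- eig$vectors[, 3L]
  lam_scaled <- 2 * eig$values[3L] / lap$lambda_max - 1
  theta <- rnorm(3)
  spec <- cheb_filter_spec(array(theta, c(1, 1, 3)))
  y <- spectral_oracle(matrix(u, ncol = 1L), lap, spec)$y
  ## scalar Chebyshev response at the scaled eigenvalue
  g <- theta[1] + theta[2] * lam_scaled + theta[3] * (2 * lam_scaled^2 - 1)
  expect_equal(as.numeric(y), g * u, tolerance = 1e-10)
})

test_that("the graph Fourier transform pair inverts exactly", {
  lap <- build_laplacian(rand_adjacency(10L, seed = 21), "normalized")
  spec <- cheb_filter_spec(array(1, c(1, 1, 1)))
  x <- matrix(rnorm(10), 10L, 1L)
  o <- spectral_oracle(x, lap, spec)
  expect_equal(o$inverse(o$transform(x)), x, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("filtering is linear in the signal", {
  sc <- scaled_from_matrix(rand_adjacency(14L, seed = 5))
  spec <- cheb_filter_spec(array(rnorm(2 * 2 * 3), c(2, 2, 3)))
  x <- matrix(rnorm(28), 14L, 2L)
  z <- matrix(rnorm(28), 14L, 2L)
  lhs <- cheb_filter(2 * x - 3 * z, sc, spec)
  rhs <- 2 * cheb_filter(x, sc, spec) - 3 * cheb_filter(z, sc, spec)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("a K=3 filter is 2-localized on a path graph", {
  n <- 30L
  sc <- scaled_from_matrix(path_adjacency(n))
  spec <- cheb_filter_spec(array(rnorm(3), c(1, 1, 3)))
  x <- matrix(rnorm(n), n, 1L)
  y0 <- cheb_filter(x, sc, spec)
  xp <- x
  xp[25L, 1L] <- xp[25L, 1L] + 10     # perturb one distant vertex
  y1 <- cheb_filter(xp, sc, spec)
  ## vertices within graph distance 2 of vertex 25 may change; others not
  changed <- which(abs(y1 - y0) > 1e-12)
  expect_true(all(changed %in% 23:27))
  expect_true(all(abs(y1[1:20] - y0[1:20]) == 0))
})

test_that("filtering is equivariant under vertex relabeling", {
  n <- 16L
  a <- rand_adjacency(n, seed = 13)
  spec <- cheb_filter_spec(array(rnorm(2 * 2 * 3), c(2, 2, 3)))
  x <- matrix(rnorm(n * 2), n, 2L)
  set.seed(1)
  perm <- sample(n)
  ap <- a[perm, perm]
  ## the fixed lambda_max convention makes the operator itself permutation
  ## equivariant (the power-iteration estimate depends weakly on labeling)
  sc <- scale_laplacian(build_laplacian(a, lambda_max = "fixed"))
  scp <- scale_laplacian(build_laplacian(ap, lambda_max = "fixed"))
  y <- cheb_filter(x, sc, spec)
  yp <- cheb_filter(x[perm, ], scp, spec)
  expect_lt(max(abs(yp - y[perm, ])), 1e-10)
})

test_that("the dense oracle refuses graphs above its size bound", {
  lap <- build_laplacian(rand_adjacency(30L, seed = 1), "normalized")
  spec <- cheb_filter_spec(array(1, c(1, 1, 1)))
  expect_error(spectral_oracle(matrix(0, 30, 1), lap, spec, max_n = 20L),
               "test-only")
})

test_that("filter parameter count follows F_in x F_out x K", {
  spec <- cheb_filter_spec(array(0, c(9, 32, 3)))
  expect_equal(length(spec$theta), 9L * 32L * 3L)
  expect_equal(length(spec$theta), 864L)
})
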