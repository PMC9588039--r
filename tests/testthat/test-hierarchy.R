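test_that("zero coarsening levels returns just the input graph", {
  st <- tiny_study()
  h <- coarsen(st$template_obj$template, 0L, seed = 1)
  expect_equal(h$num_levels, 0L)
  expect_equal(length(h$levels), 1L)
  expect_equal(h$levels[[1]]$n_real, st$template_obj$template$n)
})

test_that("each level halves the padded vertex count exactly", {
  st <- tiny_study()
  h <- coarsen(st$template_obj$template, 4L, seed = 1)
  np <- vapply(h$levels, `[[`, 0L, "n_padded")
  expect_equal(np[-length(np)], 2L * np[-1L])
  expect_equal(np[1L], 16L * np[5L])
})

test_that("heavy-edge matching on a path merges into clusters of at most two", {
  g <- structure(list(n = 8L, adjacency = path_adjacency(8L),
                      coordinates = cbind(1:8, 0, 0),
                      partition = data.frame(structure = rep("cortex", 8),
                                             hemisphere = rep("left", 8)),
                      component_offsets = c(cortex.left = 0L),
                      component_counts = c(cortex.left = 8L)),
                 class = "template_graph")
  h <- coarsen(g, 1L, seed = 2)
  l1 <- h$levels[[2]]
  expect_gte(l1$n_real, 4L)
  expect_lte(l1$n_real, 5L)                 # singletons allowed at the ends
  expect_equal(l1$n_padded * 2L, h$levels[[1]]$n_padded)
  ## coarse graph of a path stays connected on its real vertices
  a <- as.matrix(l1$adjacency)[!l1$fake_mask, !l1$fake_mask, drop = FALSE]
  lap <- build_laplacian(methods::as(Matrix::Matrix(a, sparse = TRUE),
                                     "CsparseMatrix"), "combinatorial")
  ev <- eigen(as.matrix(lap$matrix), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 1L)    # one zero eigenvalue = connected
})

test_that("coarsening is deterministic given the seed", {
  st <- tiny_study()
  h1 <- coarsen(st$template_obj$template, 2L, seed = 7)
  h2 <- coarsen(st$template_obj$template, 2L, seed = 7)
  expect_identical(h1$perm0, h2$perm0)
  expect_equal(h1$levels[[3]]$adjacency, h2$levels[[3]]$adjacency)
})

test_that("fake vertices carry no edges and every real vertex has one parent", {
  st <- tiny_study()
  h <- coarsen(st$template_obj$template, 3L, seed = 1)
  for (lev in h$levels) {
    deg <- Matrix::rowSums(lev$adjacency)
    expect_true(all(deg[lev$fake_mask] == 0))
  }
  ## level-0 permutation covers every template vertex exactly once
  p <- h$perm0[!h$levels[[1]]$fake_mask]
  expect_setequal(p, seq_len(st$template_obj$template$n))
})

test_that("max pooling takes sibling maxima with fake children neutral", {
  fake_h <- structure(list(
    levels = list(list(n_padded = 4L, n_real = 4L,
                       fake_mask = c(FALSE, FALSE, FALSE, FALSE)),
                  list(n_padded = 2L, n_real = 2L,
                       fake_mask = c(FALSE, FALSE))),
    num_levels = 1L), class = "graph_hierarchy")
  out <- pool_features(matrix(c(1, 5, 2, 4)), fake_h, level = 0L)
  expect_equal(as.numeric(out), c(5, 4))
  ## a fake sibling never wins, even when its stored value is larger
  fake_h$levels[[1]]$fake_mask <- c(FALSE, TRUE, FALSE, FALSE)
  out2 <- pool_features(matrix(c(1, 99, 2, 4)), fake_h, level = 0L)
  expect_equal(as.numeric(out2), c(1, 4))
  ## constant fields stay constant
  outc <- pool_features(matrix(3, 4, 2), fake_h, level = 0L)
  expect_true(all(outc[1, ] == 3))
  expect_error(pool_features(matrix(0, 3, 1), fake_h, 0L), "padded vertices")
})

test_that("pooling is invariant under swapping siblings within a pair", {
  st <- tiny_study()
  h <- coarsen(st$template_obj$template, 2L, seed = 1)
  np <- h$levels[[1]]$n_padded
  set.seed(5)
  x <- matrix(rnorm(np * 3), np, 3L)
  swapped <- x
  sw <- as.vector(rbind(seq(2, np, 2), seq(1, np, 2)))
  swapped <- x[sw, , drop = FALSE]
  hsw <- h
  hsw$levels[[1]]$fake_mask <- h$levels[[1]]$fake_mask[sw]
  expect_equal(pool_features(swapped, hsw, 0L), pool_features(x, h, 0L))
})

test_that("upsampling preserves constants and the value range", {
  st <- tiny_study()
  h <- coarsen(st$template_obj$template, 2L, seed = 1)
  nl <- h$levels[[3]]$n_real
  expect_equal(upsample_map(rep(2.5, nl), h), rep(2.5, st$template_obj$template$n))
  set.seed(8)
  v <- runif(nl)
  up <- upsample_map(v, h)
  expect_equal(length(up), st$template_obj$template$n)
  expect_gte(min(up), min(v) - 1e-12)
  expect_lte(max(up), max(v) + 1e-12)
})

test_that("a one-hot coarse map stays local to descendants and their ring", {
  st <- tiny_study()
  tpl <- st$template_obj$template
  h <- coarsen(tpl, 2L, seed = 1)
  lev <- h$levels[[3]]
  v <- numeric(lev$n_padded)
  src <- which(!lev$fake_mask)[1L]
  v[src] <- 1
  up <- upsample_map(v, h, from_level = 2L)
  ## descendants of the source supernode at level 0
  kids0 <- ((src - 1L) * 4L + 1L):(src * 4L)
  real0 <- kids0[!h$levels[[1]]$fake_mask[kids0]]
  desc <- h$levels[[1]]$perm[real0]
  ## support must stay within descendants plus their 1-ring neighborhood
  nb <- unique(c(desc, which(Matrix::rowSums(
    tpl$adjacency[, desc, drop = FALSE]) > 0)))
  expect_true(all(which(up > 1e-12) %in% nb))
  expect_gt(sum(up), 0)
})

test_that("upsampling accepts real-count input and checks lengths", {
  st <- tiny_study()
  h <- coarsen(st$template_obj$template, 2L, seed = 1)
  lev <- h$levels[[3]]
  expect_equal(length(upsample_map(runif(lev$n_real), h)), st$template_obj$template$n)
  expect_error(upsample_map(runif(lev$n_padded + 1L), h), "matches neither")
  expect_error(upsample_map(runif(4), h, from_level = 9L), "out of range")
})

test_that("interpolation weights are a row-stochastic nonnegative operator", {
  st <- tiny_study()
  h <- coarsen(st$template_obj$template, 1L, seed = 1)
  w <- h$interp
  expect_true(all(w@x >= 0))
  expect_equal(as.numeric(Matrix::rowSums(w)), rep(1, nrow(w)), tolerance = 1e-12)
})

test_that("normalized Laplacian spectra stay in [0, 2] across random graphs", {
  for (s in 1:20) {
    n <- sample(5:25, 1)
    lap <- build_laplacian(rand_adjacency(n, p = 0.4, seed = 300 + s),
                           "normalized")
    ev <- eigen(as.matrix(lap$matrix), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_lte(max(ev), 2 + 1e-8)
  }
})
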