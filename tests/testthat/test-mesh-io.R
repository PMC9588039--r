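test_that("PLY round trip preserves a tetrahedron in both encodings", {
  m <- tetra_mesh()
  for (bin in c(TRUE, FALSE)) {
    path <- tempfile(fileext = ".ply")
    write_surface(m, path, "ply", binary = bin)
    r <- read_surface(path, "ply", structure = "amygdala")
    expect_equal(nrow(r$vertices), 4L)
    expect_equal(nrow(r$faces), 4L)
    expect_lt(max(abs(r$vertices - m$vertices)), 1e-6)
    expect_identical(r$faces, m$faces)
    unlink(path)
  }
})

test_that("FreeSurfer and GIfTI round trips preserve coordinates to 1e-6", {
  ic <- icosphere(1L)
  m <- surface_mesh(ic$vertices * 10, ic$faces, "cortex_inner", "left")
  for (fmt in c("freesurfer", "gifti")) {
    path <- tempfile(fileext = if (fmt == "gifti") ".surf.gii" else ".white")
    write_surface(m, path, fmt)
    r <- read_surface(path, fmt, structure = "cortex_inner")
    expect_lt(max(abs(r$vertices - m$vertices)), 1e-6)
    expect_identical(r$faces, m$faces)
    unlink(path)
  }
})

test_that("format auto-detection uses the file extension", {
  m <- tetra_mesh()
  path <- tempfile(fileext = ".ply")
  write_surface(m, path, "ply")
  r <- read_surface(path, structure = "amygdala")
  expect_lt(max(abs(r$vertices - m$vertices)), 1e-12)
  unlink(path)
})

test_that("truncated or missing files raise I/O errors, never partial meshes", {
  expect_error(read_surface(tempfile(), "ply"), "does not exist")
  m <- tetra_mesh()
  for (fmt in c("freesurfer", "ply")) {
    path <- tempfile()
    write_surface(m, path, fmt)
    raw <- readBin(path, "raw", file.size(path))
    writeBin(raw[seq_len(length(raw) - 20L)], path)
    expect_error(read_surface(path, fmt), "truncat")
    unlink(path)
  }
})

test_that("meshes with invalid topology are rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(surface_mesh(v, rbind(c(1, 2, 5))), "out of range")
  expect_error(surface_mesh(v, rbind(c(1, 2, 2))), "degenerate")
  expect_error(surface_mesh(v[1:3, ], rbind(c(1, 2, 3))), "more than 3")
})

test_that("rigid_align is the identity for an already-aligned mesh", {
  m <- tetra_mesh()
  out <- rigid_align(m, m)
  expect_lt(max(abs(out$vertices - m$vertices)), 1e-9)
  expect_lt(max(abs(attr(out, "rotation") - diag(3))), 1e-9)
})

test_that("rigid_align recovers a known rotation and translation", {
  ic <- icosphere(1L)
  tpl <- surface_mesh(ic$vertices * 10, ic$faces, "thalamus", "left")
  th <- 30 * pi / 180
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L)
  moved <- tpl
  moved$vertices <- sweep(tpl$vertices %*% t(rz), 2L, c(5, 0, 0), `+`)
  back <- rigid_align(moved, tpl)
  expect_lt(max(abs(back$vertices - tpl$vertices)), 1e-6)
  expect_equal(det(attr(back, "rotation")), 1, tolerance = 1e-9)
})

test_that("rigid_align never introduces a reflection", {
  ic <- icosphere(1L)
  ## a chiral deformation of the sphere so reflection would fit better
  v <- ic$vertices * 10
  v[, 1] <- v[, 1] + 0.3 * v[, 2]^2
  tpl <- surface_mesh(v, ic$faces, "putamen", "left")
  mirrored <- tpl
  mirrored$vertices[, 1] <- -mirrored$vertices[, 1]
  out <- rigid_align(mirrored, tpl)
  expect_equal(det(attr(out, "rotation")), 1, tolerance = 1e-9)
  expect_gt(mean((out$vertices - tpl$vertices)^2), 1e-4)
})

test_that("rigid_align is idempotent", {
  st <- tiny_study()
  tpl <- st$template_obj$meshes[["cortex_inner.left"]]
  subj <- st$cohort[[1]]$meshes[["cortex_inner.left"]]
  a1 <- rigid_align(subj, tpl)
  a2 <- rigid_align(a1, tpl)
  expect_lt(max(abs(a2$vertices - a1$vertices)), 1e-9)
})

test_that("template assembly builds a block-diagonal union in canonical order", {
  m1 <- tetra_mesh("amygdala", "left")
  m2 <- tetra_mesh("caudate", "left", shift = c(10, 0, 0))
  g <- assemble_template_graph(list(m1, m2))
  expect_equal(g$n, 8L)
  ## canonical order is alphabetical by subcortical structure
  expect_equal(names(g$component_offsets), c("amygdala.left", "caudate.left"))
  a <- as.matrix(g$adjacency)
  expect_true(all(a[1:4, 5:8] == 0))
  expect_true(all(a == t(a)))
  expect_true(all(diag(a) == 0))
  expect_equal(sum(a > 0) / 2, 12)          # two tetrahedra, 6 edges each
  ## permuting the input order leaves the graph unchanged
  g2 <- assemble_template_graph(list(m2, m1))
  expect_equal(as.matrix(g2$adjacency), a)
  expect_identical(g2$partition, g$partition)
  ## a single structure reproduces its own edge graph
  g1 <- assemble_template_graph(list(m1))
  expect_equal(sum(as.matrix(g1$adjacency) > 0) / 2, 6)
  ## duplicate structures are rejected
  expect_error(assemble_template_graph(list(m1, m1)), "duplicate")
})

test_that("feature encoding follows the zero-padded 9-dimensional layout", {
  st <- tiny_study()
  tpl <- st$template_obj$template
  subj <- st$cohort[[1]]
  x <- encode_features(subj, tpl, "combined")
  expect_equal(ncol(x), 9L)
  expect_true(all(x >= 0 & x <= 1))
  cortical <- tpl$partition$structure == "cortex"
  expect_true(all(x[!cortical, 4:9] == 0))   # subcortical rows: last 6 zero
  expect_true(all(x[cortical, 1:3] == 0))    # cortical rows: first 3 zero
  expect_true(any(x[!cortical, 1:3] != 0))
  expect_true(any(x[cortical, 4:9] != 0))
})

test_that("cortical-only encoding gives 6 features per node", {
  st <- tiny_study()
  meshes <- st$template_obj$meshes
  cort <- meshes[grepl("^cortex", names(meshes))]
  tpl_c <- assemble_template_graph(cort)
  x <- encode_features(cort, tpl_c, "cortical_only")
  expect_equal(ncol(x), 6L)
  expect_true(all(x >= 0 & x <= 1))
  expect_error(encode_features(cort, tpl_c, "subcortical_only"),
               "not used by mode")
})

test_that("a degenerate coordinate axis is mapped to zero", {
  m1 <- tetra_mesh("amygdala", "left")
  m1$vertices[, 3] <- 0                      # flat in z
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  m1 <- surface_mesh(m1$vertices, f, "amygdala", "left")
  g <- assemble_template_graph(list(m1))
  x <- encode_features(list(m1), g, "subcortical_only")
  expect_true(all(x[, 3] == 0))
  expect_true(all(x >= 0 & x <= 1))
})

test_that("score tables round trip through delimited text", {
  d <- data.frame(subject_id = c("s1", "s2"), score = c(1.5, -2))
  path <- tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  r <- read_scores(path)
  expect_equal(r$subject_id, c("s1", "s2"))
  expect_equal(r$score, c(1.5, -2))
  unlink(path)
  expect_error(read_scores(tempfile()), "does not exist")
})
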