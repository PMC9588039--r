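## Shared fixtures, built in code and cached for the session.

fixture_env <- new.env(parent = emptyenv())

## symmetric 0/1 random adjacency as dgCMatrix
rand_adjacency <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n) < p, n, n)
  a <- a | t(a)
  diag(a) <- FALSE
  methods::as(Matrix::Matrix(a * 1.0, sparse = TRUE), "CsparseMatrix")
}

## connected path graph adjacency
path_adjacency <- function(n) {
  i <- seq_len(n - 1L)
  methods::as(Matrix::sparseMatrix(i = c(i, i + 1L), j = c(i + 1L, i), x = 1,
                                   dims = c(n, n)), "CsparseMatrix")
}

## tetrahedron mesh (smallest closed triangulation)
tetra_mesh <- function(structure = "amygdala", hemisphere = "left",
                       shift = c(0, 0, 0)) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  surface_mesh(sweep(v, 2L, shift, `+`), f, structure = structure,
               hemisphere = hemisphere)
}

## small synthetic template + cohort + prepared dataset, built once
tiny_study <- function(n_subjects = 24L, seed = 11L) {
  key <- sprintf("tiny_%d_%d", n_subjects, seed)
  if (is.null(fixture_env[[key]])) {
    spec <- synthetic_spec(cortex_subdivisions = 1L,
                           subcortical_subdivisions = 0L,
                           n_subjects = n_subjects, seed = seed)
    tpl <- generate_template(spec)
    cohort <- generate_cohort(tpl)
    ds <- prepare_dataset(cohort, tpl$template, mode = "combined",
                          num_levels = 2L, seed = seed)
    fixture_env[[key]] <- list(spec = spec, template_obj = tpl,
                               cohort = cohort, dataset = ds)
  }
  fixture_env[[key]]
}

## small trained-free model on the tiny study
tiny_model <- function(seed = 3L) {
  st <- tiny_study()
  build_model(gcnn_model_config(9L, channels = c(4L, 4L, 6L, 6L), K = 3L,
                                dropout_rate = 0, seed = seed),
              st$dataset$hierarchy)
}

scaled_from_matrix <- function(m, lambda_max = 2) {
  lap <- build_laplacian(m, "normalized")
  scale_laplacian(lap)
}
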