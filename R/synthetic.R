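# ---------------------------------------------------------------------------
# Synthetic template meshes and cohorts with a planted morphology -> score
# effect, so the whole pipeline can be exercised without any imaging data.
# ---------------------------------------------------------------------------

#' Unit icosphere mesh
#'
#' Subdivided icosahedron projected onto the unit sphere;
#' `10 * 4^depth + 2` vertices. Deterministic triangulation.
#'
#' @param depth subdivision depth (>= 0).
#' @return list with `vertices` (unit norm) and `faces`.
#' @export
icosphere <- function(depth = 0L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (d in seq_len(depth)) {
    nv <- nrow(v)
    midpoint <- new.env(parent = emptyenv())
    verts <- v
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- midpoint[[key]]
      if (is.null(id)) {
        m <- (verts[a, ] + verts[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        verts <<- rbind(verts, m)
        id <- nrow(verts)
        midpoint[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c <- f[i, 3L]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  list(vertices = v, faces = f)
}

#' Synthetic cohort specification
#'
#' Defaults are the package's reference study conditions for end-to-end
#' validation: depth-3 icosphere hemisphere stand-ins (642 vertices each,
#' inner radius 50 mm, outer 52 mm), 14 depth-1 subcortical spheres
#' (42 vertices, radius 10 mm), 300 subjects; the planted effect displaces a
#' geodesic cap of angular radius 0.7 rad on the left hemisphere radially by
#' a Gaussian-profile bump whose amplitude (SD 2 mm) maps to the score with
#' slope 1 score-unit/mm; score noise SD is 0.2 of the signal SD; smooth
#' nuisance deformation (10 random spherical harmonics of degree <= 4,
#' radial SD 0.5 mm) is added everywhere.
#'
#' @param cortex_subdivisions,subcortical_subdivisions icosphere depths.
#' @param n_subjects cohort size (>= 2).
#' @param effect_hemisphere hemisphere carrying the planted bump.
#' @param effect_center_vertex cap centre (vertex index on the hemisphere
#'   mesh); `NULL` (default) picks the mesh vertex nearest
#'   `effect_center_direction`.
#' @param effect_center_direction unit direction of the cap centre on the
#'   hemisphere sphere. The default diagonal `(-1, 1, 1)/sqrt(3)` is
#'   maximally distant from all three coordinate axes, so the bump cannot
#'   touch the per-subject per-axis coordinate extremes that define the
#'   min-max feature normalization — the planted effect stays genuinely
#'   local instead of leaking into every vertex's normalized coordinates
#'   through the normalization denominator.
#' @param effect_radius cap angular radius in radians.
#' @param effect_beta score units per mm of bump amplitude.
#' @param bump_amplitude_sd SD of the per-subject bump amplitude (mm).
#' @param nuisance_sd radial SD of the smooth nuisance field (mm).
#' @param nuisance_degree maximum harmonic degree of the nuisance field.
#' @param noise_sd score noise SD; default 0.2 * |effect_beta| *
#'   `bump_amplitude_sd`.
#' @param seed integer seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(cortex_subdivisions = 3L,
                           subcortical_subdivisions = 1L,
                           n_subjects = 300L,
                           effect_hemisphere = "left",
                           effect_center_vertex = NULL,
                           effect_center_direction = c(-1, 1, 1) / sqrt(3),
                           effect_radius = 0.7,
                           effect_beta = 1,
                           bump_amplitude_sd = 2,
                           nuisance_sd = 0.5,
                           nuisance_degree = 4L,
                           noise_sd = NULL,
                           seed = 1L) {
  if (is.null(noise_sd)) noise_sd <- 0.2 * abs(effect_beta) * bump_amplitude_sd
  stopifnot(n_subjects >= 2L, bump_amplitude_sd >= 0, nuisance_sd >= 0,
            noise_sd >= 0, effect_radius > 0)
  structure(list(cortex_subdivisions = as.integer(cortex_subdivisions),
                 subcortical_subdivisions = as.integer(subcortical_subdivisions),
                 n_subjects = as.integer(n_subjects),
                 effect_hemisphere = match.arg(effect_hemisphere, HEMISPHERES),
                 effect_center_vertex = if (is.null(effect_center_vertex))
                   NULL else as.integer(effect_center_vertex),
                 effect_center_direction = effect_center_direction /
                   sqrt(sum(effect_center_direction^2)),
                 effect_radius = effect_radius,
                 effect_beta = effect_beta,
                 bump_amplitude_sd = bump_amplitude_sd,
                 nuisance_sd = nuisance_sd,
                 nuisance_degree = as.integer(nuisance_degree),
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## fixed layout of the synthetic head: sphere centres and radii (mm)
synth_layout <- function() {
  sub_centers <- list(
    accumbens = c(12, 8, -12), amygdala = c(28, -2, -18),
    caudate = c(14, 10, 8), hippocampus = c(30, -22, -14),
    pallidum = c(20, 0, 0), putamen = c(26, 4, -4), thalamus = c(12, -18, 6))
  list(cortex_center = function(h) c(if (h == "left") -55 else 55, 0, 0),
       cortex_r_inner = 50, cortex_r_outer = 52,
       sub_center = function(s, h) {
         b <- sub_centers[[s]]
         c(if (h == "left") -b[1L] else b[1L], b[2L], b[3L])
       },
       sub_r = 10)
}

#' Generate the synthetic registered template
#'
#' Two subdivided icospheres stand in for the left/right cortical
#' hemispheres, each emitted twice as an "inner" and an "outer" surface
#' (radii 50 and 52 mm, shared triangulation), plus 14 small icospheres for
#' the seven subcortical structures per hemisphere. All subjects generated
#' from this template share the triangulation; only vertex coordinates vary.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `meshes` (named list of [surface_mesh()]), `template`
#'   (the assembled `template_graph`) and `spec`.
#' @export
generate_template <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lay <- synth_layout()
  ico_c <- icosphere(spec$cortex_subdivisions)
  ico_s <- icosphere(spec$subcortical_subdivisions)
  meshes <- list()
  for (h in HEMISPHERES) {
    ctr <- lay$cortex_center(h)
    meshes[[paste0("cortex_inner.", h)]] <- surface_mesh(
      sweep(ico_c$vertices * lay$cortex_r_inner, 2L, ctr, `+`), ico_c$faces,
      structure = "cortex_inner", hemisphere = h)
    meshes[[paste0("cortex_outer.", h)]] <- surface_mesh(
      sweep(ico_c$vertices * lay$cortex_r_outer, 2L, ctr, `+`), ico_c$faces,
      structure = "cortex_outer", hemisphere = h)
    for (s in SUBCORTICAL_STRUCTURES) {
      meshes[[paste(s, h, sep = ".")]] <- surface_mesh(
        sweep(ico_s$vertices * lay$sub_r, 2L, lay$sub_center(s, h), `+`),
        ico_s$faces, structure = s, hemisphere = h)
    }
  }
  template <- assemble_template_graph(meshes)
  list(meshes = meshes, template = template, spec = spec)
}

## unit directions of a sphere mesh about its centre
sphere_dirs <- function(vertices, center) {
  d <- sweep(vertices, 2L, center)
  d / sqrt(rowSums(d^2))
}

## smooth random field on the sphere: 10 random directional polynomials of
## degree <= nuisance_degree (a random linear combination of spherical
## harmonics up to that degree), standardized to unit SD over the vertices
random_harmonic_field <- function(dirs, degree) {
  field <- numeric(nrow(dirs))
  for (j in 1:10) {
    a <- rnorm(3L)
    a <- a / sqrt(sum(a^2))
    d <- sample.int(degree, 1L)
    field <- field + rnorm(1L) * (dirs %*% a)^d
  }
  s <- sd(field)
  if (s > 0) field <- (field - mean(field)) / s
  as.numeric(field)
}

## cap centre vertex: explicit index, or the mesh vertex nearest the
## configured direction
resolve_effect_center <- function(dirs, spec) {
  if (!is.null(spec$effect_center_vertex)) {
    if (spec$effect_center_vertex < 1L ||
        spec$effect_center_vertex > nrow(dirs))
      stop("effect region centre lies outside the template mesh")
    return(spec$effect_center_vertex)
  }
  which.max(dirs %*% spec$effect_center_direction)
}

#' Vertices of the planted effect region
#'
#' Template-graph vertex indices of the geodesic cap carrying the planted
#' bump, plus the cap membership on the hemisphere mesh itself.
#'
#' @param template_obj result of [generate_template()].
#' @param spec the [synthetic_spec()] (defaults to the template's).
#' @return list with `graph_vertices` (indices into the template graph),
#'   `mesh_vertices` (indices into the hemisphere mesh) and `center_vertex`.
#' @export
effect_region_vertices <- function(template_obj, spec = template_obj$spec) {
  lay <- synth_layout()
  h <- spec$effect_hemisphere
  mesh <- template_obj$meshes[[paste0("cortex_inner.", h)]]
  dirs <- sphere_dirs(mesh$vertices, lay$cortex_center(h))
  center <- resolve_effect_center(dirs, spec)
  c0 <- dirs[center, ]
  theta <- acos(pmin(pmax(dirs %*% c0, -1), 1))
  mesh_idx <- which(theta <= spec$effect_radius)
  off <- template_obj$template$component_offsets[[paste0("cortex_inner.", h)]]
  list(graph_vertices = mesh_idx + off, mesh_vertices = mesh_idx,
       center_vertex = center)
}

#' Generate a synthetic cohort with a planted shape-score effect
#'
#' Per subject: a bump amplitude `a ~ N(0, bump_amplitude_sd)` radially
#' displaces the effect-region cap with a Gaussian profile
#' (`exp(-theta^2 / (2 * (radius/2)^2))`, applied coherently to the inner
#' and outer surface); a smooth random harmonic field displaces every
#' structure radially (nuisance); the recorded raw score is
#' `effect_beta * a + N(0, noise_sd)`. Same seed, same cohort, bit for bit.
#'
#' @param template_obj result of [generate_template()].
#' @param spec a [synthetic_spec()] (defaults to the template's).
#' @return list of [subject_record()]s; the planted amplitudes are attached
#'   as attribute `amplitudes`.
#' @export
generate_cohort <- function(template_obj, spec = template_obj$spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lay <- synth_layout()
  meshes0 <- template_obj$meshes
  h_eff <- spec$effect_hemisphere
  eff_mesh <- meshes0[[paste0("cortex_inner.", h_eff)]]
  dirs_eff <- sphere_dirs(eff_mesh$vertices, lay$cortex_center(h_eff))
  c0 <- dirs_eff[resolve_effect_center(dirs_eff, spec), ]
  theta <- acos(pmin(pmax(dirs_eff %*% c0, -1), 1))
  profile <- as.numeric(exp(-theta^2 / (2 * (spec$effect_radius / 2)^2)))
  ## per-mesh unit directions about each structure's own centre
  centers <- lapply(names(meshes0), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    if (startsWith(parts[1L], "cortex")) lay$cortex_center(parts[2L])
    else lay$sub_center(parts[1L], parts[2L])
  })
  names(centers) <- names(meshes0)
  dirs <- lapply(names(meshes0), function(k)
    sphere_dirs(meshes0[[k]]$vertices, centers[[k]]))
  names(dirs) <- names(meshes0)
  set.seed(spec$seed)
  subjects <- vector("list", spec$n_subjects)
  amplitudes <- numeric(spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    a <- rnorm(1L, sd = spec$bump_amplitude_sd)
    amplitudes[i] <- a
    ## one nuisance field per structure-hemisphere; the cortical ribbon
    ## (inner + outer) shares its hemisphere's field
    fields <- list()
    for (h in HEMISPHERES) {
      if (spec$nuisance_sd > 0) {
        fields[[paste0("cortex.", h)]] <- spec$nuisance_sd *
          random_harmonic_field(dirs[[paste0("cortex_inner.", h)]],
                                spec$nuisance_degree)
        for (s in SUBCORTICAL_STRUCTURES)
          fields[[paste(s, h, sep = ".")]] <- spec$nuisance_sd *
            random_harmonic_field(dirs[[paste(s, h, sep = ".")]],
                                  spec$nuisance_degree)
      }
    }
    meshes <- meshes0
    for (k in names(meshes)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
      fkey <- if (startsWith(parts[1L], "cortex"))
        paste0("cortex.", parts[2L]) else k
      disp <- if (spec$nuisance_sd > 0) fields[[fkey]]
              else numeric(nrow(meshes[[k]]$vertices))
      if (startsWith(parts[1L], "cortex") && parts[2L] == h_eff)
        disp <- disp + a * profile
      if (any(disp != 0))
        meshes[[k]]$vertices <- meshes[[k]]$vertices + dirs[[k]] * disp
    }
    score <- spec$effect_beta * a + rnorm(1L, sd = spec$noise_sd)
    subjects[[i]] <- subject_record(sprintf("synth%04d", i), meshes, score)
  }
  attr(subjects, "amplitudes") <- amplitudes
  subjects
}
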