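#' @useDynLib surfgcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as is new
#' @importFrom stats coef cor cov lm median pnorm predict pt qnorm qt quantile
#'   residuals rnorm runif sd t.test p.adjust fitted
#' @importFrom utils head read.csv write.csv tail
NULL

## Fixed structure vocabulary and concatenation order. Cortical graph nodes
## are shared between the inner (white) and outer (pial) surface meshes, so
## the graph-level label is "cortex"; meshes carry cortex_inner/cortex_outer.
MESH_STRUCTURES <- c("cortex_inner", "cortex_outer", "amygdala", "accumbens",
                     "caudate", "hippocampus", "pallidum", "putamen",
                     "thalamus")
SUBCORTICAL_STRUCTURES <- c("accumbens", "amygdala", "caudate", "hippocampus",
                            "pallidum", "putamen", "thalamus")
HEMISPHERES <- c("left", "right")

#' Triangulated surface mesh
#'
#' Container for a single registered surface: per-vertex 3-D coordinates in
#' millimetres plus a triangle list. All subjects in a study share one
#' triangulation per structure; only the coordinates differ.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param structure one of `"cortex_inner"`, `"cortex_outer"`, `"amygdala"`,
#'   `"accumbens"`, `"caudate"`, `"hippocampus"`, `"pallidum"`, `"putamen"`,
#'   `"thalamus"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, structure = "cortex_inner",
                         hemisphere = "left") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  structure <- match.arg(structure, MESH_STRUCTURES)
  hemisphere <- match.arg(hemisphere, HEMISPHERES)
  if (ncol(vertices) != 3L)
    stop("vertices must have 3 columns (x, y, z)")
  if (nrow(vertices) <= 3L)
    stop("a surface mesh needs more than 3 vertices")
  if (ncol(faces) != 3L)
    stop("faces must be triangles (3 columns)")
  if (any(!is.finite(vertices)))
    stop("vertex coordinates must be finite")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
            faces[, 2L] == faces[, 3L]))
      stop("degenerate face: repeated vertex within a triangle")
  }
  structure(list(vertices = vertices, faces = faces,
                 structure = structure, hemisphere = hemisphere),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %s (%s), %d vertices, %d faces\n",
              x$structure, x$hemisphere, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

## Undirected edge list (2-column, i < j) induced by the triangulation.
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# ---------------------------------------------------------------------------
# Surface file formats
# ---------------------------------------------------------------------------

#' Read a surface mesh from disk
#'
#' Supports FreeSurfer binary triangle surfaces, GIfTI surface files
#' (`.surf.gii`, ASCII / Base64 / gzipped Base64 encodings) and PLY
#' (ASCII and binary little-endian). Vertex order is preserved.
#'
#' @param path file path.
#' @param format `"freesurfer"`, `"gifti"` or `"ply"`; `"auto"` guesses from
#'   the file extension.
#' @inheritParams surface_mesh
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "gifti", "ply"),
                         structure = "cortex_inner", hemisphere = "left") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read surface: file '%s' does not exist", path))
  if (format == "auto") {
    format <- if (grepl("\\.gii$", path, ignore.case = TRUE)) "gifti"
    else if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply"
    else "freesurfer"
  }
  vf <- switch(format,
               freesurfer = read_freesurfer_surface(path),
               gifti = read_gifti_surface(path),
               ply = read_ply_surface(path))
  surface_mesh(vf$vertices, vf$faces, structure = structure,
               hemisphere = hemisphere)
}

#' Write a surface mesh to disk
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"freesurfer"`, `"gifti"` or `"ply"`.
#' @param binary for PLY: write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = c("freesurfer", "gifti", "ply"),
                          binary = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(mesh, "surface_mesh"))
  switch(format,
         freesurfer = write_freesurfer_surface(mesh, path),
         gifti = write_gifti_surface(mesh, path),
         ply = write_ply_surface(mesh, path, binary = binary))
  invisible(path)
}

## FreeSurfer binary triangle surface: 3-byte magic 0xFFFFFE, a comment
## terminated by "\n\n", big-endian int32 vertex/face counts, float32
## vertex coordinates, int32 zero-based face indices.
read_freesurfer_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(magic) < 3L || !all(magic == c(255L, 255L, 254L)))
    stop(sprintf("'%s' is not a FreeSurfer triangle surface", path))
  ## comment: bytes until "\n\n"
  prev <- as.raw(0L)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop(sprintf("truncated FreeSurfer surface '%s'", path))
    if (b == as.raw(10L) && prev == as.raw(10L)) break
    prev <- b
  }
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L || any(counts < 0L))
    stop(sprintf("truncated FreeSurfer surface '%s'", path))
  nv <- counts[1L]; nf <- counts[2L]
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf)
    stop(sprintf("truncated FreeSurfer surface '%s'", path))
  list(vertices = matrix(v, ncol = 3L, byrow = TRUE),
       faces = matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

write_freesurfer_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255L, 255L, 254L)), con)
  writeBin(charToRaw("created by surfgcnn\n\n"), con)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
}

## GIfTI surface: XML with a POINTSET and a TRIANGLE data array.
read_gifti_surface <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "cannot parse GIfTI file '%s': %s", path, conditionMessage(e))))
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (length(arrays) == 0L)
    stop(sprintf("'%s' contains no GIfTI data arrays", path))
  verts <- NULL; faces <- NULL
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    vals <- decode_gifti_array(a, path)
    if (identical(intent, "NIFTI_INTENT_POINTSET")) verts <- vals
    if (identical(intent, "NIFTI_INTENT_TRIANGLE")) faces <- vals
  }
  if (is.null(verts) || is.null(faces))
    stop(sprintf("'%s' lacks a POINTSET or TRIANGLE array", path))
  list(vertices = verts, faces = matrix(as.integer(faces), ncol = 3L) + 1L)
}

decode_gifti_array <- function(node, path) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  n0 <- as.integer(xml2::xml_attr(node, "Dim0"))
  n1 <- as.integer(xml2::xml_attr(node, "Dim1"))
  if (is.na(n1)) n1 <- 1L
  dat_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(dat_node)
  size <- if (identical(dtype, "NIFTI_TYPE_FLOAT64")) 8L else 4L
  what <- if (identical(dtype, "NIFTI_TYPE_INT32")) "integer" else "numeric"
  vals <- switch(enc,
    ASCII = as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1L]]),
    Base64Binary = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      readBin(raw, what, n = n0 * n1, size = size, endian = "little")
    },
    GZipBase64Binary = {
      raw <- memDecompress(jsonlite::base64_dec(gsub("[[:space:]]", "", txt)),
                           type = "gzip")
      readBin(raw, what, n = n0 * n1, size = size, endian = "little")
    },
    stop(sprintf("unsupported GIfTI encoding '%s' in '%s'", enc, path)))
  if (length(vals) != n0 * n1)
    stop(sprintf("truncated GIfTI data array in '%s'", path))
  byrow <- !identical(order, "ColumnMajorOrder")
  matrix(vals, nrow = n0, ncol = n1, byrow = byrow)
}

write_gifti_surface <- function(mesh, path) {
  fmt_mat <- function(m, digits) paste(
    apply(m, 1L, function(r) paste(format(r, digits = digits,
                                          scientific = FALSE, trim = TRUE),
                                   collapse = " ")),
    collapse = "\n")
  v <- fmt_mat(mesh$vertices, digits = 10L)
  f <- fmt_mat(mesh$faces - 1L, digits = 12L)
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    '<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT32" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="',
    nrow(mesh$vertices), '" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n',
    "<Data>", v, "</Data>\n</DataArray>\n",
    '<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32" ',
    'ArrayIndexingOrder="RowMajorOrder" Dimensionality="2" Dim0="',
    nrow(mesh$faces), '" Dim1="3" Encoding="ASCII" Endian="LittleEndian">\n',
    "<Data>", f, "</Data>\n</DataArray>\n</GIFTI>\n")
  writeLines(xml, path, useBytes = TRUE)
}

## PLY, ASCII or binary little-endian; vertex properties x y z
## (float or double) and triangular faces as "property list uchar int".
read_ply_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readBin(con, "raw", n = 1L)
    if (length(line) == 0L) stop(sprintf("truncated PLY header in '%s'", path))
    buf <- raw()
    while (length(line) && line != as.raw(10L)) {
      buf <- c(buf, line)
      line <- readBin(con, "raw", n = 1L)
    }
    header <- c(header, trimws(rawToChar(buf)))
    if (tail(header, 1L) == "end_header") break
    if (length(header) > 200L) stop(sprintf("malformed PLY header in '%s'", path))
  }
  if (header[1L] != "ply") stop(sprintf("'%s' is not a PLY file", path))
  fmt_line <- grep("^format ", header, value = TRUE)[1L]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop(sprintf("unsupported PLY format in '%s' (ascii or binary LE only)", path))
  el <- grep("^element ", header)
  get_count <- function(name) {
    ln <- grep(paste0("^element ", name, " "), header, value = TRUE)
    if (!length(ln)) stop(sprintf("PLY file '%s' lacks element '%s'", path, name))
    as.integer(strsplit(ln[1L], " ")[[1L]][3L])
  }
  nv <- get_count("vertex"); nf <- get_count("face")
  ## vertex property types (only leading x,y,z used)
  vel <- el[grepl("^element vertex", header[el])]
  vprops <- character()
  i <- vel + 1L
  while (i <= length(header) && grepl("^property ", header[i])) {
    vprops <- c(vprops, header[i]); i <- i + 1L
  }
  vtypes <- vapply(strsplit(vprops, " "), `[`, "", 2L)
  vsizes <- ifelse(vtypes %in% c("double", "float64"), 8L, 4L)
  if (binary) {
    vraw <- readBin(con, "raw", n = nv * sum(vsizes))
    if (length(vraw) < nv * sum(vsizes))
      stop(sprintf("truncated PLY vertex data in '%s'", path))
    offs <- cumsum(c(0L, vsizes))
    stride <- sum(vsizes)
    verts <- matrix(0, nv, 3L)
    for (j in 1:3) {
      idx <- as.vector(outer(seq_len(vsizes[j]), (seq_len(nv) - 1L) * stride +
                               offs[j], `+`))
      verts[, j] <- readBin(vraw[idx], "numeric", n = nv, size = vsizes[j],
                            endian = "little")
    }
    fraw <- readBin(con, "raw", n = nf * 13L)
    if (length(fraw) < nf * 13L)
      stop(sprintf("truncated PLY face data in '%s'", path))
    cnt <- as.integer(fraw[(seq_len(nf) - 1L) * 13L + 1L])
    if (any(cnt != 3L))
      stop(sprintf("non-triangular face in PLY file '%s'", path))
    idx <- as.vector(outer(2:13, (seq_len(nf) - 1L) * 13L, `+`))
    faces <- matrix(readBin(fraw[idx], "integer", n = 3L * nf, size = 4L,
                            endian = "little"), ncol = 3L, byrow = TRUE)
  } else {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < nv + nf)
      stop(sprintf("truncated PLY body in '%s'", path))
    vtab <- do.call(rbind, lapply(strsplit(trimws(txt[seq_len(nv)]),
                                           "[[:space:]]+"), as.numeric))
    verts <- vtab[, 1:3, drop = FALSE]
    ftab <- lapply(strsplit(trimws(txt[nv + seq_len(nf)]), "[[:space:]]+"),
                   as.integer)
    if (any(vapply(ftab, `[`, 0L, 1L) != 3L))
      stop(sprintf("non-triangular face in PLY file '%s'", path))
    faces <- do.call(rbind, lapply(ftab, function(r) r[2:4]))
  }
  list(vertices = verts, faces = faces + 1L)
}

write_ply_surface <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian 1.0" else "ascii 1.0"
  header <- c("ply", paste("format", fmt),
              paste("element vertex", nv),
              "property double x", "property double y", "property double z",
              paste("element face", nf),
              "property list uchar int vertex_indices", "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- t(mesh$faces) - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[, i]), con, size = 4L, endian = "little")
    }
  } else {
    v <- apply(mesh$vertices, 1L, function(r)
      paste(format(r, digits = 17L, scientific = FALSE, trim = TRUE),
            collapse = " "))
    f <- apply(mesh$faces - 1L, 1L, function(r)
      paste(c(3L, r), collapse = " "))
    writeBin(charToRaw(paste0(paste(c(v, f), collapse = "\n"), "\n")), con)
  }
}

# ---------------------------------------------------------------------------
# Rigid alignment
# ---------------------------------------------------------------------------

#' Rigidly align a mesh to a template
#'
#' Least-squares rigid-body registration (rotation + translation, no scaling,
#' no reflection) of a subject mesh onto the template it corresponds to
#' vertex-by-vertex, preserving anatomy. The optimal proper rotation is the
#' orthogonal-Procrustes solution with the determinant constrained to +1.
#'
#' @param mesh subject [surface_mesh()].
#' @param template template [surface_mesh()] with identical vertex count and
#'   index correspondence.
#' @return the aligned mesh; attributes `rotation` (3x3) and
#'   `translation` (length 3) carry the applied transform
#'   (`aligned = mesh %*% t(R) + t`).
#' @export
rigid_align <- function(mesh, template) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(template, "surface_mesh"))
  if (nrow(mesh$vertices) != nrow(template$vertices))
    stop("vertex-count mismatch: mesh and template are not in correspondence")
  x <- mesh$vertices
  y <- template$vertices
  cx <- colMeans(x); cy <- colMeans(y)
  h <- crossprod(sweep(x, 2L, cx), sweep(y, 2L, cy))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # proper rotation, det +1
  tr <- cy - as.vector(r %*% cx)
  out <- mesh
  out$vertices <- sweep(x %*% t(r), 2L, tr, `+`)
  attr(out, "rotation") <- r
  attr(out, "translation") <- tr
  out
}

# ---------------------------------------------------------------------------
# Template graph
# ---------------------------------------------------------------------------

#' Assemble the combined template graph
#'
#' Builds the disjoint union of the per-structure mesh graphs: vertices are
#' template vertices, edges are triangulation edges, and no edge crosses a
#' structure boundary. Cortical graph nodes are defined by the (shared)
#' inner-surface triangulation; the outer surface contributes features, not
#' extra nodes. The concatenation order is fixed: left cortex, right cortex,
#' then each subcortical structure in alphabetical order
#' (accumbens, amygdala, caudate, hippocampus, pallidum, putamen, thalamus),
#' left hemisphere before right.
#'
#' @param meshes list of [surface_mesh()] objects, at most one per
#'   (structure, hemisphere) pair.
#' @param weighted if `TRUE`, edge weights are inverse Euclidean edge lengths;
#'   default unit weights.
#' @return an object of class `template_graph` with fields `n`, `adjacency`
#'   (sparse symmetric `dgCMatrix`), `coordinates`, `partition` (data.frame
#'   with `structure`, `hemisphere`) and `component_offsets`.
#' @export
assemble_template_graph <- function(meshes, weighted = FALSE) {
  stopifnot(is.list(meshes), length(meshes) > 0L)
  key <- vapply(meshes, function(m) paste(m$structure, m$hemisphere, sep = "."),
                "")
  if (anyDuplicated(key))
    stop(sprintf("duplicate structure in template assembly: %s",
                 key[duplicated(key)][1L]))
  names(meshes) <- key
  ## canonical ordering of graph components
  comp <- character()
  for (h in HEMISPHERES)
    if (paste0("cortex_inner.", h) %in% key)
      comp <- c(comp, paste0("cortex_inner.", h))
  for (s in SUBCORTICAL_STRUCTURES)
    for (h in HEMISPHERES)
      if (paste(s, h, sep = ".") %in% key) comp <- c(comp, paste(s, h, sep = "."))
  if (!length(comp))
    stop("no cortex_inner or subcortical meshes supplied")
  counts <- vapply(comp, function(k) nrow(meshes[[k]]$vertices), 0L)
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  names(offsets) <- comp
  n <- sum(counts)
  ii <- integer(); jj <- integer(); ww <- numeric()
  structure_lab <- character(n); hemi_lab <- character(n)
  coords <- matrix(0, n, 3L)
  for (k in seq_along(comp)) {
    m <- meshes[[comp[k]]]
    off <- offsets[k]
    idx <- off + seq_len(counts[k])
    lab <- if (m$structure == "cortex_inner") "cortex" else m$structure
    structure_lab[idx] <- lab
    hemi_lab[idx] <- m$hemisphere
    coords[idx, ] <- m$vertices
    e <- mesh_edges(m$faces)
    if (nrow(e)) {
      w <- if (weighted) {
        d <- sqrt(rowSums((m$vertices[e[, 1L], , drop = FALSE] -
                             m$vertices[e[, 2L], , drop = FALSE])^2))
        1 / pmax(d, .Machine$double.eps)
      } else rep(1, nrow(e))
      ii <- c(ii, e[, 1L] + off, e[, 2L] + off)
      jj <- c(jj, e[, 2L] + off, e[, 1L] + off)
      ww <- c(ww, w, w)
    }
  }
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  structure(list(
    n = n,
    adjacency = as(a, "generalMatrix"),
    coordinates = coords,
    partition = data.frame(structure = structure_lab, hemisphere = hemi_lab,
                           stringsAsFactors = FALSE),
    component_offsets = offsets,
    component_counts = counts
  ), class = "template_graph")
}

#' @export
print.template_graph <- function(x, ...) {
  cat(sprintf("template_graph: %d vertices, %d undirected edges, %d components\n",
              x$n, length(x$adjacency@x) / 2L, length(x$component_offsets)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Feature encoding
# ---------------------------------------------------------------------------

#' Encode per-node input features for a subject
#'
#' Assigns each template-graph node the Cartesian coordinates of the
#' subject's corresponding surface vertices and min-max normalizes them to
#' \[0, 1\]. Layouts: `cortical_only` gives 6 features per node (inner
#' x,y,z then outer x,y,z); `subcortical_only` gives 3; `combined` gives a
#' 9-dimensional zero-padded vector per node (subcortical nodes carry their
#' coordinates in entries 1..3 and zeros in 4..9; cortical nodes carry zeros
#' in 1..3 and inner/outer coordinates in 4..9).
#'
#' Normalization is per subject and per coordinate axis, pooled over all
#' vertices of the structures active in the mode; an axis with zero range
#' maps to 0.
#'
#' @param meshes named list of the subject's aligned [surface_mesh()] objects
#'   (or a `subject_record`).
#' @param template a `template_graph` built with [assemble_template_graph()]
#'   from the same structure set.
#' @param mode `"cortical_only"`, `"subcortical_only"` or `"combined"`.
#' @param normalize set `FALSE` to keep raw millimetre coordinates (used
#'   internally before augmentation).
#' @return an `n x f` numeric matrix with attributes `mode` and `f`.
#' @export
encode_features <- function(meshes, template,
                            mode = c("combined", "cortical_only",
                                     "subcortical_only"),
                            normalize = TRUE) {
  mode <- match.arg(mode)
  if (inherits(meshes, "subject_record")) meshes <- meshes$meshes
  key <- vapply(meshes, function(m) paste(m$structure, m$hemisphere, sep = "."),
                "")
  names(meshes) <- key
  f <- switch(mode, cortical_only = 6L, subcortical_only = 3L, combined = 9L)
  n <- template$n
  x <- matrix(0, n, f)
  comp <- names(template$component_offsets)
  for (k in seq_along(comp)) {
    parts <- strsplit(comp[k], ".", fixed = TRUE)[[1L]]
    s <- parts[1L]; h <- parts[2L]
    off <- template$component_offsets[k]
    cnt <- template$component_counts[k]
    idx <- off + seq_len(cnt)
    if (s == "cortex_inner") {
      if (mode == "subcortical_only")
        stop("template contains cortical structures not used by mode")
      inner <- meshes[[paste0("cortex_inner.", h)]]
      outer <- meshes[[paste0("cortex_outer.", h)]]
      if (is.null(inner) || is.null(outer))
        stop(sprintf("missing cortex_inner/cortex_outer meshes (%s) for mode '%s'",
                     h, mode))
      if (nrow(inner$vertices) != cnt)
        stop("subject cortical mesh vertex count does not match the template")
      cols <- if (mode == "combined") 4:9 else 1:6
      x[idx, cols[1:3]] <- inner$vertices
      x[idx, cols[4:6]] <- outer$vertices
    } else {
      if (mode == "cortical_only")
        stop("template contains subcortical structures not used by mode")
      m <- meshes[[comp[k]]]
      if (is.null(m))
        stop(sprintf("missing mesh for structure %s required by mode '%s'",
                     comp[k], mode))
      if (nrow(m$vertices) != cnt)
        stop("subject subcortical mesh vertex count does not match the template")
      x[idx, 1:3] <- m$vertices
    }
  }
  if (normalize) {
    ## per-axis min-max over every coordinate triple active in this mode
    for (ax in 1:3) {
      cols <- seq(ax, f, by = 3L)
      sel <- x[, cols, drop = FALSE]
      live <- !vapply(seq_len(ncol(sel)), function(j) all(sel[, j] == 0), TRUE)
      ## zero-padded entries are structural, not coordinates; exclude rows that
      ## are padding for each column block using the partition
      vals <- numeric(0)
      if (mode == "combined") {
        subc <- template$partition$structure != "cortex"
        vals <- c(x[subc, ax], x[!subc, 3L + ax], x[!subc, 6L + ax])
      } else {
        vals <- as.vector(sel)
      }
      rng <- range(vals)
      den <- rng[2L] - rng[1L]
      for (j in cols) {
        if (mode == "combined") {
          rows <- if (j <= 3L) template$partition$structure != "cortex"
                  else template$partition$structure == "cortex"
        } else rows <- rep(TRUE, n)
        x[rows, j] <- if (den > 0) (x[rows, j] - rng[1L]) / den else 0
      }
    }
  }
  attr(x, "mode") <- mode
  attr(x, "f") <- f
  x
}

#' Subject record
#'
#' Bundles a subject's registered meshes with its identifier and trait score.
#'
#' @param subject_id character scalar.
#' @param meshes list of [surface_mesh()] objects resampled onto the template
#'   triangulation.
#' @param raw_score finite numeric trait score in its native units.
#' @param normalized_score optional Gaussianized score (filled by
#'   [quantile_normalize()] during preparation).
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(subject_id, meshes, raw_score,
                           normalized_score = NA_real_) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.list(meshes), is.finite(raw_score))
  structure(list(subject_id = subject_id, meshes = meshes,
                 raw_score = as.numeric(raw_score),
                 normalized_score = as.numeric(normalized_score)),
            class = "subject_record")
}

#' Read a subject score table
#'
#' Delimited text with a header line `subject_id,score`.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return data.frame with columns `subject_id` (character), `score` (numeric).
#' @export
read_scores <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("score table '%s' does not exist", path))
  d <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "score") %in% names(d)))
    stop(sprintf("'%s' must have columns subject_id, score", path))
  if (any(!is.finite(d$score))) stop("non-finite scores in score table")
  d$subject_id <- as.character(d$subject_id)
  d[c("subject_id", "score")]
}
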