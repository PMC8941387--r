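#' Construct a triangulated face mesh
#'
#' A face mesh is a triangulated surface: a vertex coordinate matrix (mm)
#' and a triangle index matrix. At construction, degenerate triangles
#' (area < 1e-10 mm^2) are dropped with a warning and basic validity
#' (index range, connectivity) is checked.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates in mm.
#' @param triangles integer m x 3 matrix of 1-based vertex indices.
#' @param check_connected if `TRUE`, require a single connected component.
#' @return An object of class `face_mesh`.
#' @export
face_mesh <- function(vertices, triangles, check_connected = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3L)
  if (ncol(vertices) != 3L) stopf("vertices must be an n x 3 matrix")
  if (!all(is.finite(vertices))) stopf("mesh has non-finite vertex coordinates")
  if (nrow(triangles) < 1L) stopf("mesh has an empty triangle list")
  if (min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    stopf("triangle indices out of range [1, %d]", nrow(vertices))
  }
  areas <- triangle_areas(vertices, triangles)
  bad <- areas < 1e-10
  if (any(bad)) {
    warnf("dropping %d degenerate triangle(s) with area < 1e-10 mm^2", sum(bad))
    triangles <- triangles[!bad, , drop = FALSE]
    if (nrow(triangles) == 0L) stopf("all triangles degenerate")
  }
  mesh <- structure(list(vertices = vertices, triangles = triangles),
                    class = "face_mesh")
  if (check_connected && !mesh_connected(mesh)) {
    stopf("mesh is not a single connected component")
  }
  mesh
}

#' @export
print.face_mesh <- function(x, ...) {
  cat(sprintf("<face_mesh> %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), facial_area(x)))
  invisible(x)
}

# Per-triangle areas by the cross-product formula.
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c_ <- vertices[triangles[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_connected <- function(mesh) {
  el <- rbind(mesh$triangles[, c(1L, 2L)], mesh$triangles[, c(2L, 3L)],
              mesh$triangles[, c(1L, 3L)])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  used <- sort(unique(as.vector(mesh$triangles)))
  comp <- igraph::components(g)
  length(unique(comp$membership[used])) == 1L
}

#' Euclidean distance between two 3D points
#'
#' @param p,q numeric length-3 coordinate vectors (mm).
#' @return Straight-line distance in mm.
#' @export
euclidean_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != 3L || length(q) != 3L) stopf("points must be length-3")
  if (!all(is.finite(p)) || !all(is.finite(q))) stopf("non-finite coordinates")
  sqrt(sum((p - q)^2))
}

#' Total facial surface area
#'
#' Sum of the areas of all mesh triangles, in mm^2. Invariant under rigid
#' motion of the mesh.
#'
#' @param mesh a [face_mesh()].
#' @return Surface area in mm^2.
#' @export
facial_area <- function(mesh) {
  stopifnot(inherits(mesh, "face_mesh"))
  if (nrow(mesh$triangles) == 0L) stopf("mesh has an empty triangle list")
  sum(triangle_areas(mesh$vertices, mesh$triangles))
}

#' Read a triangulated mesh from an ASCII OBJ or PLY file
#'
#' Supports triangles only. The format is chosen by file extension
#' (`.obj` / `.ply`).
#'
#' @param path file path.
#' @param check_connected passed to [face_mesh()].
#' @return A [face_mesh()].
#' @export
read_mesh <- function(path, check_connected = TRUE) {
  if (!file.exists(path)) stopf("mesh file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path, check_connected),
         ply = read_ply(path, check_connected),
         stopf("unsupported mesh format '.%s' (use .obj or .ply)", ext))
}

#' Write a mesh to an ASCII OBJ or PLY file
#'
#' @param mesh a [face_mesh()].
#' @param path output path ending in `.obj` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "face_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stopf("unsupported mesh format '.%s' (use .obj or .ply)", ext))
  invisible(path)
}

read_obj <- function(path, check_connected = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L) {
    stopf("malformed OBJ file '%s': no vertices or no faces", path)
  }
  verts <- t(vapply(strsplit(sub("^v\\s+", "", vlines), "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  face_tok <- strsplit(sub("^f\\s+", "", flines), "\\s+")
  if (any(lengths(face_tok) != 3L)) {
    stopf("OBJ file '%s' contains non-triangular faces", path)
  }
  # OBJ faces may carry v/vt/vn references; keep the vertex index only
  tris <- t(vapply(face_tok,
                   function(x) as.integer(sub("/.*$", "", x)), integer(3)))
  if (any(is.na(verts)) || any(is.na(tris))) stopf("malformed OBJ file '%s'", path)
  face_mesh(verts, tris, check_connected)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# triangulated face mesh (mm)", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
}

read_ply <- function(path, check_connected = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1L]) != "ply") {
    stopf("malformed PLY file '%s': missing 'ply' magic", path)
  }
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stopf("malformed PLY file '%s': no end_header", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr))) {
    stopf("PLY file '%s' is not ASCII format", path)
  }
  nv <- as.integer(sub("^element\\s+vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)[1L]))
  nf <- as.integer(sub("^element\\s+face\\s+", "", grep("^element face", hdr, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) stopf("malformed PLY header in '%s'", path)
  body <- trimws(lines[(hdr_end + 1L):length(lines)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stopf("PLY file '%s' truncated", path)
  verts <- t(vapply(strsplit(body[seq_len(nv)], "\\s+"),
                    function(x) as.numeric(x[1:3]), numeric(3)))
  ftok <- strsplit(body[nv + seq_len(nf)], "\\s+")
  tris <- t(vapply(ftok, function(x) {
    n <- as.integer(x[1L])
    if (is.na(n) || n != 3L) stopf("PLY file contains a non-triangular face")
    as.integer(x[2:4]) + 1L  # PLY indices are 0-based
  }, integer(3)))
  face_mesh(verts, tris, check_connected)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
}

# Rigidly transform a mesh (rotation matrix + translation, optional scale).
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- scale * (mesh$vertices %*% t(rotation))
  v <- sweep(v, 2, translation, FUN = "+")
  out <- mesh
  out$vertices <- v
  out
}
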