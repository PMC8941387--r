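## Thin-plate splines -------------------------------------------------------

# 2D TPS height interpolation: kernel U(r) = r^2 log r.
tps2d_fit <- function(xy, z) {
  n <- nrow(xy)
  r <- as.matrix(stats::dist(xy))
  K <- ifelse(r > 0, r^2 * log(r), 0)
  P <- cbind(1, xy)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(M, c(z, numeric(3)))
  list(xy = xy, w = sol[seq_len(n)], a = sol[n + 1:3])
}

tps2d_eval <- function(fit, xy) {
  xy <- as.matrix(xy)
  d2 <- outer(xy[, 1], fit$xy[, 1], "-")^2 + outer(xy[, 2], fit$xy[, 2], "-")^2
  r <- sqrt(d2)
  U <- ifelse(r > 0, d2 * log(r), 0)  # r^2 log r
  as.vector(U %*% fit$w + cbind(1, xy) %*% fit$a)
}

# 3D TPS deformation (biharmonic kernel U(r) = r), mapping the control
# points `from` exactly onto `to`; applied to arbitrary point sets.
tps3d_fit <- function(from, to) {
  n <- nrow(from)
  K <- as.matrix(stats::dist(from))
  P <- cbind(1, from)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  sol <- solve(M, rbind(to, matrix(0, 4, 3)))
  list(from = from, w = sol[seq_len(n), , drop = FALSE],
       a = sol[n + 1:4, , drop = FALSE])
}

tps3d_eval <- function(fit, pts) {
  pts <- as.matrix(pts)
  d2 <- outer(rowSums(pts^2), rowSums(fit$from^2), "+") - 2 * pts %*% t(fit$from)
  d2[d2 < 0] <- 0
  sqrt(d2) %*% fit$w + cbind(1, pts) %*% fit$a
}

## Fixture meshes ------------------------------------------------------------

#' Geometric fixture meshes
#'
#' Deterministic meshes with known geometry, used as oracles for the
#' distance and area computations and as the substrate for synthetic faces:
#'
#' * `"plane"`: a flat triangulated square of side 100 mm at z = 0;
#'   `resolution` = grid cells per side (default 20).
#' * `"unit_sphere"`: an icosphere of radius 1 centred at the origin;
#'   `resolution` = subdivision level (default 3, 1280 triangles).
#' * `"face_template"`: a smooth face-like height-field surface
#'   interpolating the 21 template landmarks (thin-plate spline over an
#'   elliptical domain), with every landmark an exact mesh vertex;
#'   `resolution` = grid spacing in mm (default 5). Pass `landmarks` to
#'   deform the template surface onto a subject's landmark set.
#'
#' @param kind one of `"plane"`, `"unit_sphere"`, `"face_template"`.
#' @param resolution resolution parameter, per kind (see above).
#' @param landmarks optional [landmark_set()]; for `"face_template"` the
#'   template surface is TPS-deformed so this subject's landmarks lie on it.
#' @return A [face_mesh()]. For `"face_template"`, the element
#'   `landmark_vertices` names the vertex index of each landmark.
#' @export
fixture_mesh <- function(kind = c("plane", "unit_sphere", "face_template"),
                         resolution = NULL, landmarks = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         plane = plane_mesh(resolution %||% 20L),
         unit_sphere = icosphere(resolution %||% 3L),
         face_template = face_template_mesh(resolution %||% 5, landmarks))
}

# Square grid with centre-split cells (4 triangles per cell), so both
# diagonal directions are represented everywhere; this keeps the
# directional quantization error of graph geodesics low.
plane_mesh <- function(n = 20L, side = 100) {
  n <- as.integer(n)
  if (n < 1L) stopf("plane resolution must be >= 1 cell per side")
  s <- seq(0, side, length.out = n + 1L)
  g <- expand.grid(x = s, y = s)
  nv <- nrow(g)
  i <- rep(seq_len(n), n)
  j <- rep(seq_len(n), each = n)
  h <- side / n
  ctr <- cbind((i - 0.5) * h, (j - 0.5) * h)
  verts <- cbind(rbind(as.matrix(g), ctr), 0)
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  a <- idx(i, j); b <- idx(i + 1L, j); c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  m <- nv + seq_along(i)
  face_mesh(verts, rbind(cbind(a, b, m), cbind(b, c_, m),
                         cbind(c_, d, m), cbind(d, a, m)))
}

icosphere <- function(level = 3L) {
  level <- as.integer(level)
  if (level < 0L) stopf("sphere subdivision level must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    nv <- nrow(v)
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
    key <- lo * (nv + 1) + hi
    uk <- !duplicated(key)
    mids <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    mid_id <- nv + match(key, key[uk])
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  face_mesh(v, f)
}

# Elliptical face domain used by the template surface (mm).
face_domain <- function() list(a = 80, b = 105, cy = 8, rim_z = -25, rim_n = 16L)

face_template_mesh <- function(spacing = 5, landmarks = NULL) {
  if (spacing <= 0) stopf("face mesh grid spacing must be > 0 mm")
  dom <- face_domain()
  tmpl <- face_template("female")
  # grid offset by half a cell so no landmark sits exactly on a grid line
  xs <- seq(-dom$a + spacing / 2, dom$a, by = spacing)
  ys <- seq(dom$cy - dom$b + spacing / 2, dom$cy + dom$b, by = spacing)
  g <- expand.grid(x = xs, y = ys)
  inside <- (g$x / dom$a)^2 + ((g$y - dom$cy) / dom$b)^2 <= 1
  keep_id <- which(inside)
  remap <- match(seq_len(nrow(g)), keep_id)
  nx <- length(xs)
  i <- rep(seq_len(nx - 1L), length(ys) - 1L)
  j <- rep(seq_len(length(ys) - 1L), each = nx - 1L)
  idx <- function(i, j) (j - 1L) * nx + i
  quads <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  ok <- rowSums(matrix(inside[quads], ncol = 4L)) == 4L
  quads <- quads[ok, , drop = FALSE]
  tris <- rbind(quads[, c(1L, 2L, 3L)], quads[, c(1L, 3L, 4L)])
  tris <- matrix(remap[tris], ncol = 3L)
  xy <- cbind(g$x[keep_id], g$y[keep_id])

  # insert each landmark (x, y) as an exact vertex via 1-to-3 triangle split
  lm_xy <- tmpl$points[, 1:2, drop = FALSE]
  lm_vertex <- integer(nrow(lm_xy))
  for (li in seq_len(nrow(lm_xy))) {
    p <- lm_xy[li, ]
    t_id <- locate_triangle_2d(xy, tris, p)
    if (is.na(t_id)) stopf("landmark '%s' falls outside the face domain",
                           rownames(lm_xy)[li])
    xy <- rbind(xy, p)
    new_v <- nrow(xy)
    tv <- tris[t_id, ]
    tris <- rbind(tris[-t_id, , drop = FALSE],
                  c(tv[1L], tv[2L], new_v),
                  c(tv[2L], tv[3L], new_v),
                  c(tv[3L], tv[1L], new_v))
    lm_vertex[li] <- new_v
  }
  names(lm_vertex) <- rownames(lm_xy)

  # height field: TPS through the 21 landmarks plus a receding boundary rim
  th <- seq(0, 2 * pi, length.out = dom$rim_n + 1L)[-1L]
  rim <- cbind(dom$a * cos(th), dom$cy + dom$b * sin(th))
  fit <- tps2d_fit(rbind(lm_xy, rim),
                   c(tmpl$points[, 3], rep(dom$rim_z, dom$rim_n)))
  z <- tps2d_eval(fit, xy)
  z[lm_vertex] <- tmpl$points[, 3]  # exact, guard against round-off
  verts <- cbind(xy, z)

  # drop slivers produced by near-edge landmark insertion
  areas <- triangle_areas(verts, tris)
  tris <- tris[areas >= 1e-8, , drop = FALSE]
  mesh <- face_mesh(verts, tris, check_connected = FALSE)
  mesh$landmark_vertices <- lm_vertex
  if (!is.null(landmarks)) mesh <- mesh_from_landmarks(landmarks, mesh)
  mesh
}

# Index of the triangle whose 2D projection contains point p (barycentric
# test over all triangles).
locate_triangle_2d <- function(xy, tris, p) {
  ax <- xy[tris[, 1L], 1L]; ay <- xy[tris[, 1L], 2L]
  bx <- xy[tris[, 2L], 1L]; by <- xy[tris[, 2L], 2L]
  cx <- xy[tris[, 3L], 1L]; cy <- xy[tris[, 3L], 2L]
  d <- (by - cy) * (ax - cx) + (cx - bx) * (ay - cy)
  w1 <- ((by - cy) * (p[1L] - cx) + (cx - bx) * (p[2L] - cy)) / d
  w2 <- ((cy - ay) * (p[1L] - cx) + (ax - cx) * (p[2L] - cy)) / d
  w3 <- 1 - w1 - w2
  hit <- which(w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9 & abs(d) > 1e-12)
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L]
}

#' Deform the template face surface onto a subject's landmarks
#'
#' Thin-plate-spline warp of a template face mesh carrying landmark
#' vertices: the deformation maps the template landmarks exactly onto the
#' subject's landmarks, so every subject landmark lies on (is a vertex of)
#' the returned mesh.
#'
#' @param landmarks a [landmark_set()] for the subject.
#' @param template a face-template mesh from
#'   `fixture_mesh("face_template")`; built at default resolution if omitted.
#' @return A [face_mesh()] with `landmark_vertices` preserved.
#' @export
mesh_from_landmarks <- function(landmarks, template = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (is.null(template)) template <- fixture_mesh("face_template")
  if (is.null(template$landmark_vertices)) {
    stopf("template mesh does not carry landmark vertices")
  }
  from <- template$vertices[template$landmark_vertices, , drop = FALSE]
  to <- landmarks$points[names(template$landmark_vertices), , drop = FALSE]
  fit <- tps3d_fit(from, to)
  out <- template
  out$vertices <- tps3d_eval(fit, template$vertices)
  out$vertices[template$landmark_vertices, ] <- to  # exact at landmarks
  out
}
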