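#' Build a geodesic shortest-path graph for a mesh
#'
#' Approximates on-surface (geodesic) distances by Dijkstra shortest paths
#' on an enriched edge graph: the graph nodes are the mesh vertices plus
#' `edge_points` equally spaced interior points on every mesh edge, and
#' within each triangle all boundary nodes are pairwise connected by
#' straight segments. Paths can therefore cut across triangle interiors,
#' which bounds the chordal overestimate of the true polyhedral geodesic;
#' accuracy improves roughly quadratically in `edge_points + 1`.
#'
#' @param mesh a [face_mesh()].
#' @param edge_points number of interior nodes per mesh edge (>= 0).
#' @return An object of class `geodesic_graph` (the igraph, node
#'   coordinates, and per-triangle node index table), reusable across
#'   queries on the same mesh.
#' @export
geodesic_graph <- function(mesh, edge_points = 4L) {
  stopifnot(inherits(mesh, "face_mesh"))
  k <- as.integer(edge_points)
  if (k < 0L) stopf("edge_points must be >= 0")
  v <- mesh$vertices
  tri <- mesh$triangles
  nv <- nrow(v)

  # unique undirected mesh edges, keyed for triangle -> edge lookup
  e_all <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  lo <- pmin(e_all[, 1L], e_all[, 2L])
  hi <- pmax(e_all[, 1L], e_all[, 2L])
  key <- lo * (nv + 1) + hi
  ukey <- !duplicated(key)
  edges <- cbind(lo[ukey], hi[ukey])
  ne <- nrow(edges)
  edge_id <- match(key, key[ukey])  # per tri-edge (3 blocks of ntri)

  # node coordinates: mesh vertices then edge-interior points
  if (k > 0L) {
    fr <- seq_len(k) / (k + 1)
    p1 <- v[edges[, 1L], , drop = FALSE]
    p2 <- v[edges[, 2L], , drop = FALSE]
    interior <- do.call(rbind, lapply(fr, function(f) p1 * (1 - f) + p2 * f))
    coords <- rbind(v, interior)
  } else {
    coords <- v
  }
  # node ids of the interior points of edge e: nv + (j-1)*ne + e, j = 1..k
  edge_nodes <- function(e) {
    if (k == 0L) return(matrix(integer(0), nrow = length(e)))
    vapply(seq_len(k), function(j) nv + (j - 1L) * ne + e, integer(length(e)))
  }

  ntri <- nrow(tri)
  m <- 3L + 3L * k
  tri_nodes <- matrix(0L, ntri, m)
  tri_nodes[, 1:3] <- tri
  if (k > 0L) {
    tri_nodes[, 3L + seq_len(k)]          <- edge_nodes(edge_id[seq_len(ntri)])
    tri_nodes[, 3L + k + seq_len(k)]      <- edge_nodes(edge_id[ntri + seq_len(ntri)])
    tri_nodes[, 3L + 2L * k + seq_len(k)] <- edge_nodes(edge_id[2L * ntri + seq_len(ntri)])
  }

  # all node pairs within each triangle
  prs <- combn(m, 2L)
  a <- as.vector(tri_nodes[, prs[1L, ]])
  b <- as.vector(tri_nodes[, prs[2L, ]])
  glo <- pmin(a, b); ghi <- pmax(a, b)
  keep <- !duplicated(glo * (nrow(coords) + 1) + ghi)
  glo <- glo[keep]; ghi <- ghi[keep]
  w <- sqrt(rowSums((coords[glo, , drop = FALSE] - coords[ghi, , drop = FALSE])^2))
  pos <- w > 0
  g <- igraph::make_graph(c(rbind(glo[pos], ghi[pos])), n = nrow(coords),
                          directed = FALSE)
  igraph::E(g)$weight <- w[pos]

  structure(list(graph = g, coords = coords, tri_nodes = tri_nodes,
                 mesh = mesh, edge_points = k),
            class = "geodesic_graph")
}

#' Closest point on a mesh surface
#'
#' Exact point-to-triangle projection over all mesh triangles.
#'
#' @param mesh a [face_mesh()].
#' @param p query point (length-3, mm).
#' @return List with `point` (closest surface point), `triangle` (index)
#'   and `distance` (mm from `p` to the surface).
#' @export
closest_surface_point <- function(mesh, p) {
  stopifnot(inherits(mesh, "face_mesh"))
  p <- as.numeric(p)
  cp <- closest_points_on_triangles(mesh$vertices, mesh$triangles, p)
  d2 <- rowSums(sweep(cp, 2, p)^2)
  i <- which.min(d2)
  list(point = cp[i, ], triangle = i, distance = sqrt(d2[i]))
}

# Vectorized closest point on each triangle to a single query point
# (Ericson, Real-Time Collision Detection, ch. 5).
closest_points_on_triangles <- function(v, tri, p) {
  a <- v[tri[, 1L], , drop = FALSE]
  b <- v[tri[, 2L], , drop = FALSE]
  c_ <- v[tri[, 3L], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  ap <- sweep(-a, 2, p, FUN = "+")
  bp <- sweep(-b, 2, p, FUN = "+")
  cp_ <- sweep(-c_, 2, p, FUN = "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  d5 <- rowSums(ab * cp_); d6 <- rowSums(ac * cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  n <- nrow(a)
  out <- matrix(NA_real_, n, 3L)
  done <- rep(FALSE, n)
  set <- function(mask, pts) {
    mask <- mask & !done
    out[mask, ] <<- pts[mask, , drop = FALSE]
    done <<- done | mask
  }
  set(d1 <= 0 & d2 <= 0, a)                                   # vertex a
  set(d3 >= 0 & d4 <= d3, b)                                  # vertex b
  set(d6 >= 0 & d5 <= d6, c_)                                 # vertex c
  t_ab <- d1 / (d1 - d3)
  set(vc <= 0 & d1 >= 0 & d3 <= 0, a + ab * t_ab)             # edge ab
  t_ac <- d2 / (d2 - d6)
  set(vb <= 0 & d2 >= 0 & d6 <= 0, a + ac * t_ac)             # edge ac
  t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + (c_ - b) * t_bc) # edge bc
  denom <- 1 / (va + vb + vc)
  set(rep(TRUE, n), a + ab * (vb * denom) + ac * (vc * denom)) # interior
  out
}

#' Geodesic distance between two points over a mesh surface
#'
#' Both points are snapped to the nearest surface point (within
#' `snap_tol` mm); the reported length is the shortest path over the
#' enriched edge graph between the two containing triangles, including the
#' straight segments from each query point to the path. The result is
#' always at least the Euclidean distance between the points.
#'
#' @param x a [face_mesh()] or a prebuilt [geodesic_graph()].
#' @param p,q query points (length-3, mm), on or near the surface.
#' @param snap_tol maximum allowed distance from the surface, in mm.
#' @return Geodesic path length in mm.
#' @export
geodesic_distance <- function(x, p, q, snap_tol = 2) {
  gg <- if (inherits(x, "geodesic_graph")) x else geodesic_graph(x)
  p <- as.numeric(p); q <- as.numeric(q)
  sp <- closest_surface_point(gg$mesh, p)
  sq <- closest_surface_point(gg$mesh, q)
  if (sp$distance > snap_tol) {
    stopf("point (%.2f, %.2f, %.2f) is %.2f mm off the surface (tolerance %g mm)",
          p[1], p[2], p[3], sp$distance, snap_tol)
  }
  if (sq$distance > snap_tol) {
    stopf("point (%.2f, %.2f, %.2f) is %.2f mm off the surface (tolerance %g mm)",
          q[1], q[2], q[3], sq$distance, snap_tol)
  }
  lead <- sqrt(sum((p - sp$point)^2)) + sqrt(sum((q - sq$point)^2))
  # a straight chord that lies on the surface is itself the shortest
  # surface path; detect this (flat regions) before running Dijkstra
  if (chord_on_surface(gg$mesh, sp$point, sq$point)) {
    return(lead + sqrt(sum((sp$point - sq$point)^2)))
  }
  # connect each endpoint to all nodes of the one-ring neighbourhood of its
  # containing triangle; the longer lead segments reduce the angular
  # quantization error of the first and last path legs
  nodes_p <- ring_nodes(gg, sp$triangle)
  nodes_q <- ring_nodes(gg, sq$triangle)
  dmat <- igraph::distances(gg$graph, v = nodes_p, to = nodes_q)
  off_p <- sqrt(rowSums(sweep(gg$coords[nodes_p, , drop = FALSE], 2, sp$point)^2))
  off_q <- sqrt(rowSums(sweep(gg$coords[nodes_q, , drop = FALSE], 2, sq$point)^2))
  best <- min(outer(off_p, off_q, "+") + dmat)
  if (!is.finite(best)) stopf("no surface path between the two points")
  direct <- if (sp$triangle == sq$triangle) {
    sqrt(sum((sp$point - sq$point)^2))
  } else Inf
  # path from p to its surface projection, across the surface, back to q
  lead + min(best, direct)
}

# TRUE if the straight segment a-b stays on the mesh surface (within a
# tight tolerance at interior sample points).
chord_on_surface <- function(mesh, a, b, n_samples = 16L, tol = 1e-6) {
  ts <- seq_len(n_samples) / (n_samples + 1)
  for (t in ts) {
    x <- (1 - t) * a + t * b
    if (closest_surface_point(mesh, x)$distance > tol) return(FALSE)
  }
  TRUE
}

# Node ids of all triangles sharing a vertex with triangle t.
ring_nodes <- function(gg, t) {
  tri <- gg$mesh$triangles
  vs <- tri[t, ]
  touch <- tri[, 1L] %in% vs | tri[, 2L] %in% vs | tri[, 3L] %in% vs
  unique(as.vector(gg$tri_nodes[touch, , drop = FALSE]))
}

#' Geodesic distance matrix for a set of points
#'
#' Batched variant of [geodesic_distance()]: each point is snapped to its
#' nearest graph node and one multi-source Dijkstra supplies all pairwise
#' path lengths. Each reported length is a valid polyline length from one
#' original point to the other, so it is never below the Euclidean
#' distance. When the points are mesh vertices (as for meshes built from a
#' landmark template) the node snap is exact.
#'
#' @param x a [face_mesh()] or prebuilt [geodesic_graph()].
#' @param points n x 3 matrix of query points (rows named).
#' @param snap_tol maximum allowed distance from the surface, in mm.
#' @return n x n symmetric matrix of path lengths (mm).
#' @export
geodesic_pairs <- function(x, points, snap_tol = 2) {
  gg <- if (inherits(x, "geodesic_graph")) x else geodesic_graph(x)
  points <- as.matrix(points)
  n <- nrow(points)
  node <- integer(n)
  off <- numeric(n)
  for (i in seq_len(n)) {
    sp <- closest_surface_point(gg$mesh, points[i, ])
    if (sp$distance > snap_tol) {
      stopf("point '%s' is %.2f mm off the surface (tolerance %g mm)",
            rownames(points)[i] %||% i, sp$distance, snap_tol)
    }
    cand <- gg$tri_nodes[sp$triangle, ]
    d2 <- rowSums(sweep(gg$coords[cand, , drop = FALSE], 2, points[i, ])^2)
    node[i] <- cand[which.min(d2)]
    off[i] <- sqrt(min(d2))
  }
  un <- unique(node)
  dmat <- igraph::distances(gg$graph, v = un, to = un)
  idx <- match(node, un)
  res <- dmat[idx, idx, drop = FALSE] + outer(off, off, "+")
  diag(res) <- 0
  if (any(!is.finite(res))) stopf("no surface path between some point pairs")
  dimnames(res) <- list(rownames(points), rownames(points))
  res
}
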