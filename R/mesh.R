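#' Greedy edge-capped surface triangulation
#'
#' Connects nearby points into a triangle mesh without bridging gaps: no
#' triangle edge may exceed `max_edge_factor` times the median
#' nearest-neighbor spacing of the input. For planar (2-column) input the
#' mesh is the Delaunay triangulation with over-long triangles removed, so
#' the covered region follows the points' footprint rather than its convex
#' fill. For 3-D input each point's neighborhood is projected onto its
#' local PCA tangent plane, locally Delaunay triangles are collected, and a
#' triangle is retained when at least two of its three vertex stars agree
#' on it — a greedy-projection construction suited to the thin, smooth
#' surfaces of leaf blades.
#'
#' @param points N x 2 or N x 3 numeric matrix (or a [point_cloud()], used
#'   in 3-D).
#' @param max_edge_factor Edge cap as a multiple of the median
#'   nearest-neighbor spacing.
#' @param k Neighborhood size for the 3-D construction.
#' @param min_spacing Known sample pitch (e.g. the voxel size that produced
#'   the points); the cap scale is `max(median NN spacing, min_spacing)`,
#'   which keeps the cap meaningful when many grid cells hold clumped
#'   representatives.
#' @return A `surface_mesh`: list with `vertices`, `triangles` (T x 3 index
#'   matrix), `areas` (per-triangle) and `area` (their sum).
#' @export
#' @examples
#' g <- as.matrix(expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1)))
#' triangulate_surface(g)$area  # 1
triangulate_surface <- function(points, max_edge_factor = 3, k = 14,
                                min_spacing = NULL) {
  if (inherits(points, "point_cloud")) points <- cloud_positions(points)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dims <- ncol(points)
  if (!dims %in% c(2L, 3L)) abort("`points` must have 2 or 3 columns.")
  points <- points[!duplicated(points), , drop = FALSE]
  n <- nrow(points)
  if (n < 3) abort("triangulation needs at least 3 distinct points.")
  nn <- RANN::nn2(points, k = 2)
  med_sp <- median(nn$nn.dists[, 2])
  if (!is.finite(med_sp) || med_sp <= 0) med_sp <- 1e-9
  if (!is.null(min_spacing)) med_sp <- max(med_sp, min_spacing)
  cap <- max_edge_factor * med_sp

  if (dims == 2L) {
    tri <- tryCatch(interp::tri.mesh(points[, 1], points[, 2]),
                    error = function(e) NULL)
    if (is.null(tri)) {
      warn("degenerate (collinear) input; returning an empty mesh.")
      return(new_surface_mesh(points, matrix(integer(0), 0, 3)))
    }
    T_ <- interp::triangles(tri)[, 1:3, drop = FALSE]
  } else {
    idx <- RANN::nn2(points, k = min(n, k + 1))$nn.idx
    T_ <- cpp_local_star_mesh(points, idx[, -1, drop = FALSE], cap, 2L)
    if (nrow(T_) == 0) {
      warn("no triangles under the edge cap; returning an empty mesh.")
      return(new_surface_mesh(points, matrix(integer(0), 0, 3)))
    }
  }
  # enforce the edge cap and drop degenerate slivers
  A <- points[T_[, 1], , drop = FALSE]
  B <- points[T_[, 2], , drop = FALSE]
  C <- points[T_[, 3], , drop = FALSE]
  e1 <- rowSums((A - B)^2); e2 <- rowSums((A - C)^2); e3 <- rowSums((B - C)^2)
  areas <- tri_areas(A, B, C)
  keep <- pmax(e1, e2, e3) <= cap^2 & areas > (1e-8 * med_sp)^2
  new_surface_mesh(points, T_[keep, , drop = FALSE], areas[keep])
}

tri_areas <- function(A, B, C) {
  if (ncol(A) == 2) {
    abs((B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) -
          (C[, 1] - A[, 1]) * (B[, 2] - A[, 2])) / 2
  } else {
    u <- B - A; v <- C - A
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
}

new_surface_mesh <- function(vertices, triangles, areas = NULL) {
  if (is.null(areas)) {
    areas <- if (nrow(triangles)) {
      tri_areas(vertices[triangles[, 1], , drop = FALSE],
                vertices[triangles[, 2], , drop = FALSE],
                vertices[triangles[, 3], , drop = FALSE])
    } else numeric(0)
  }
  structure(list(vertices = vertices, triangles = triangles,
                 areas = areas, area = sum(areas)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface mesh: %d vertices, %d triangles, total area %.4g\n",
              nrow(x$vertices), nrow(x$triangles), x$area))
  invisible(x)
}

#' @export
glance.surface_mesh <- function(x, ...) {
  tibble(n_vertices = nrow(x$vertices), n_triangles = nrow(x$triangles),
         area = x$area)
}

#' Voxel-grid down-sampling
#'
#' Keeps one representative point — the cell centroid — per occupied cube
#' (3-D) or square (2-D) of a regular grid.
#'
#' @param points N x 2 or N x 3 matrix.
#' @param size Cell edge length.
#' @return Matrix of cell centroids.
#' @export
voxel_downsample <- function(points, size) {
  points <- as.matrix(points)
  if (size <= 0) abort("`size` must be positive.")
  n <- nrow(points)
  if (n == 0) return(points)
  key <- apply(floor(sweep(points, 2, rep(size, ncol(points)), "/")), 1, paste, collapse = "_")
  f <- factor(key, levels = unique(key))
  out <- rowsum(points, f, reorder = FALSE) / as.vector(table(f))
  unname(out)
}

#' Minimum enclosing circle of 2-D points
#'
#' Exact smallest circle via Welzl's move-to-front algorithm run on the
#' convex hull vertices.
#'
#' @param xy N x 2 matrix.
#' @return List with `center` (length 2) and `radius`.
#' @export
min_enclosing_circle <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  if (n == 0) abort("no points.")
  if (n == 1) return(list(center = xy[1, ], radius = 0))
  h <- tryCatch(chull(xy), error = function(e) seq_len(n))
  if (length(h) >= 3) xy <- xy[h, , drop = FALSE]
  n <- nrow(xy)
  xy <- xy[withr::with_seed(0L, sample.int(n)), , drop = FALSE]

  in_circ <- function(c_, p) {
    !is.null(c_) && sqrt(sum((p - c_$center)^2)) <= c_$radius * (1 + 1e-10) + 1e-14
  }
  circ2 <- function(p, q) list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
  circ3 <- function(p, q, r) {
    D <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
    if (abs(D) < 1e-14) {
      # collinear: span by the farthest pair
      cands <- list(circ2(p, q), circ2(p, r), circ2(q, r))
      return(cands[[which.max(vapply(cands, `[[`, 0, "radius"))]])
    }
    sp <- sum(p^2); sq <- sum(q^2); sr <- sum(r^2)
    cx <- (sp * (q[2] - r[2]) + sq * (r[2] - p[2]) + sr * (p[2] - q[2])) / D
    cy <- (sp * (r[1] - q[1]) + sq * (p[1] - r[1]) + sr * (q[1] - p[1])) / D
    list(center = c(cx, cy), radius = sqrt((p[1] - cx)^2 + (p[2] - cy)^2))
  }

  c_ <- circ2(xy[1, ], xy[2, ])
  for (i in seq_len(n)) {
    p <- xy[i, ]
    if (in_circ(c_, p)) next
    c_ <- circ2(xy[1, ], p)
    for (j in seq_len(i - 1)) {
      q <- xy[j, ]
      if (in_circ(c_, q)) next
      c_ <- circ2(p, q)
      for (k in seq_len(j - 1)) {
        r <- xy[k, ]
        if (in_circ(c_, r)) next
        c_ <- circ3(p, q, r)
      }
    }
  }
  c_
}

polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
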