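#' Plant height of a calibrated shoot cloud
#'
#' The difference between the maximum and minimum Z coordinate.
#'
#' @param cloud A [point_cloud()] (calibrated units for a height in cm).
#' @return Height in the cloud's units.
#' @export
plant_height <- function(cloud) {
  cloud <- assert_cloud(cloud)
  if (nrow(cloud) < 1) abort("empty cloud: no height.")
  max(cloud$z) - min(cloud$z)
}

#' Projected (footprint) area
#'
#' Projects the cloud onto the XOY plane, sparsifies the projection with a
#' 2-D voxel filter (one cell-centroid representative per occupied cell),
#' triangulates the result under the edge cap and sums the triangle areas.
#' Because over-long triangles are discarded, concave footprints are
#' preserved rather than convex-filled.
#'
#' @param cloud A [point_cloud()] or an N x 2 / N x 3 matrix.
#' @param voxel_size_cm 2-D sparsification cell size.
#' @param max_edge_factor Edge cap for [triangulate_surface()].
#' @return Area in cm^2 (0 with a warning for degenerate projections).
#' @export
projected_area <- function(cloud, voxel_size_cm = 0.2, max_edge_factor = 3) {
  P <- if (inherits(cloud, "point_cloud")) cloud_positions(cloud) else as.matrix(cloud)
  xy <- P[, 1:2, drop = FALSE]
  if (nrow(xy) < 3) { warn("fewer than 3 points: projected area 0."); return(0) }
  # anchor the sparsification grid to the footprint's centroid and principal
  # axes, so the estimate is invariant to rigid motions in the plane
  # (grid-alignment jitter otherwise moves thin-blade footprints by ~1%)
  xy <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(crossprod(xy) / nrow(xy), symmetric = TRUE)$vectors
  for (j in 1:2) if (sum((xy %*% ev[, j])^3) < 0) ev[, j] <- -ev[, j]
  xy <- xy %*% ev
  v <- voxel_downsample(xy, voxel_size_cm)
  sv <- if (nrow(v) >= 3) svd(sweep(v, 2, colMeans(v)))$d else c(1, 0)
  if (nrow(v) < 3 || sv[2] < 1e-9 * sv[1]) {
    warn("degenerate projection (collinear points): projected area 0.")
    return(0)
  }
  mesh <- withCallingHandlers(
    triangulate_surface(v, max_edge_factor = max_edge_factor,
                        min_spacing = voxel_size_cm),
    warning = function(w) invokeRestart("muffleWarning"))
  mesh$area
}

#' Multi-layer projected area
#'
#' Splits the cloud's Z range into `n_layers` equal-height slabs (half-open
#' `[low, high)`, top slab closed, so each point belongs to exactly one
#' layer) and computes [projected_area()] per slab, bottom to top.
#'
#' @inheritParams projected_area
#' @param n_layers Number of equal-height layers.
#' @return Tibble with `layer`, `z_low_cm`, `z_high_cm`, `n_points`,
#'   `area_cm2`, ordered bottom to top.
#' @export
layered_projected_area <- function(cloud, n_layers = 4, voxel_size_cm = 0.2,
                                   max_edge_factor = 3) {
  cloud <- assert_cloud(cloud)
  if (n_layers < 1) abort("`n_layers` must be at least 1.")
  z <- cloud$z
  z0 <- min(z); z1 <- max(z)
  hgt <- (z1 - z0) / n_layers
  lay <- if (hgt > 0) pmin(floor((z - z0) / hgt) + 1L, n_layers) else rep(1L, length(z))
  P <- cloud_positions(cloud)
  purrr::map_dfr(seq_len(n_layers), function(i) {
    pts <- P[lay == i, , drop = FALSE]
    a <- if (nrow(pts) < 3) {
      warn(sprintf("layer %d has fewer than 3 points; area set to 0.", i))
      0
    } else {
      projected_area(pts, voxel_size_cm = voxel_size_cm, max_edge_factor = max_edge_factor)
    }
    tibble(layer = i, z_low_cm = z0 + (i - 1) * hgt, z_high_cm = z0 + i * hgt,
           n_points = nrow(pts), area_cm2 = a)
  })
}

#' Mesh-based single-sided leaf area
#'
#' Voxel-grid down-samples the cloud in 3-D, smooths it by moving least
#' squares (each point projected onto a locally fitted bivariate polynomial
#' surface of `poly_order` over its `mls_radius_cm` neighborhood), meshes
#' the smoothed points with the edge-capped greedy triangulation and sums
#' the facet areas. Thin stems do not support a local surface and largely
#' drop out of the mesh, so the total is dominated by the blades — the
#' behaviour that makes whole-shoot meshing a usable leaf-area estimate for
#' narrow-leaved plants. Points whose neighborhood is too small for the
#' polynomial fall back to a plane fit; their count is reported as an
#' attribute.
#'
#' @param cloud A [point_cloud()] in calibrated units.
#' @param voxel_size_cm 3-D voxel size for down-sampling.
#' @param mls_radius_cm Smoothing neighborhood radius.
#' @param poly_order Order of the fitted polynomial surface.
#' @param max_edge_factor Edge cap for [triangulate_surface()].
#' @param boundary_correction Add the first-order boundary-strip correction
#'   (open boundary length times half the sample spacing). A mesh over
#'   interior sample points stops about half a spacing short of the true
#'   blade edge, a bias of order `perimeter * spacing / 2` that matters for
#'   narrow blades; the correction removes it to first order.
#' @param stem_filter_ratio After smoothing, points whose neighborhood has
#'   `sqrt(lambda_min / lambda_mid)` (thickness relative to width) above
#'   this value are discarded before meshing: a smoothed blade is a thin
#'   sheet, a stem is a tube, so this is what confines the facet sum to the
#'   blades. 0 disables the filter.
#' @return Single-sided area in cm^2 with attribute `n_starved`.
#' @export
leaf_area <- function(cloud, voxel_size_cm = 0.2, mls_radius_cm = 1,
                      poly_order = 3, max_edge_factor = 3,
                      boundary_correction = TRUE, stem_filter_ratio = 0.35) {
  P <- if (inherits(cloud, "point_cloud")) cloud_positions(cloud) else as.matrix(cloud)
  if (nrow(P) < 10) abort("leaf area needs at least 10 points.")
  v <- voxel_downsample(P, voxel_size_cm)
  kmax <- min(nrow(v), 80L)
  nn <- RANN::nn2(v, k = kmax, searchtype = "radius", radius = mls_radius_cm)
  sm <- cpp_mls_smooth(v, nn$nn.idx, nn$nn.dists, mls_radius_cm,
                       as.integer(poly_order), 0)
  # smoothing collapses noise-thickened sheets onto the surface; re-voxel so
  # the mesh sees one regularly spaced sample layer
  pts <- voxel_downsample(sm$points, voxel_size_cm)
  if (stem_filter_ratio > 0 && nrow(pts) > 4) {
    nn2_ <- RANN::nn2(pts, k = min(nrow(pts), kmax), searchtype = "radius",
                      radius = mls_radius_cm)
    shape <- cpp_mls_smooth(pts, nn2_$nn.idx, nn2_$nn.dists, mls_radius_cm,
                            1L, stem_filter_ratio)
    pts <- pts[shape$keep, , drop = FALSE]
  }
  if (nrow(pts) < 3) {
    warn("no surface-supported points left after filtering; leaf area 0.")
    return(structure(0, n_starved = sm$starved))
  }
  mesh <- withCallingHandlers(
    triangulate_surface(pts, max_edge_factor = max_edge_factor,
                        min_spacing = voxel_size_cm),
    warning = function(w) invokeRestart("muffleWarning"))
  area <- mesh$area
  if (boundary_correction && nrow(mesh$triangles) > 0) {
    spacing <- median(RANN::nn2(mesh$vertices, k = 2)$nn.dists[, 2])
    area <- area + mesh_boundary_length(mesh) * spacing / 2
  }
  structure(area, n_starved = sm$starved)
}

## total length of mesh edges that belong to exactly one triangle
mesh_boundary_length <- function(mesh) {
  T_ <- mesh$triangles
  if (!nrow(T_)) return(0)
  e <- rbind(T_[, c(1, 2)], T_[, c(2, 3)], T_[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  open_ <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  if (!nrow(open_)) return(0)
  sum(sqrt(rowSums((mesh$vertices[open_[, 1], , drop = FALSE] -
                      mesh$vertices[open_[, 2], , drop = FALSE])^2)))
}

#' Convex hull volume
#'
#' Volume of the 3-D convex hull of the cloud.
#'
#' @param cloud A [point_cloud()] or N x 3 matrix.
#' @return Volume in cm^3 (0 with a warning for coplanar input).
#' @export
convex_volume <- function(cloud) {
  P <- if (inherits(cloud, "point_cloud")) cloud_positions(cloud) else as.matrix(cloud)
  P <- P[!duplicated(P), , drop = FALSE]
  if (nrow(P) < 4) abort("convex volume needs at least 4 non-coplanar points.")
  res <- cpp_convex_hull_volume(P)
  if (res$degenerate) {
    warn("coplanar cloud: convex volume 0.")
    return(0)
  }
  res$volume
}

#' Shoot compactness
#'
#' Ratio of the (concavity-preserving) projected area to the area of the
#' 2-D convex hull of the projection; values near 1 indicate a dense,
#' filled footprint, small values a spread, star-like shoot.
#'
#' @inheritParams projected_area
#' @return Compactness in `(0, 1]` (up to meshing tolerance).
#' @export
compactness <- function(cloud, voxel_size_cm = 0.2, max_edge_factor = 3) {
  P <- if (inherits(cloud, "point_cloud")) cloud_positions(cloud) else as.matrix(cloud)
  xy <- unique(P[, 1:2, drop = FALSE])
  if (nrow(xy) < 3) abort("degenerate projection: compactness undefined.")
  h <- chull(xy)
  if (length(h) < 3) abort("degenerate (collinear) projection: compactness undefined.")
  hull_area <- polygon_area(xy[h, , drop = FALSE])
  if (hull_area <= 0) abort("degenerate projection: compactness undefined.")
  pa <- projected_area(P, voxel_size_cm = voxel_size_cm, max_edge_factor = max_edge_factor)
  pa / hull_area
}

#' Trait-extraction parameters
#'
#' @param projected_voxel_cm Voxel size for the projected-area filter.
#' @param leaf_voxel_cm Voxel size for the leaf-area down-sampling.
#' @param mls_radius_cm MLS smoothing radius.
#' @param poly_order MLS polynomial order.
#' @param max_edge_factor Mesh edge cap multiplier.
#' @param n_layers Layers for the multi-layer projected area.
#' @return A `trait_params` list.
#' @export
trait_params <- function(projected_voxel_cm = 0.2, leaf_voxel_cm = 0.2,
                         mls_radius_cm = 1, poly_order = 3,
                         max_edge_factor = 3, n_layers = 4) {
  structure(list(projected_voxel_cm = projected_voxel_cm,
                 leaf_voxel_cm = leaf_voxel_cm, mls_radius_cm = mls_radius_cm,
                 poly_order = poly_order, max_edge_factor = max_edge_factor,
                 n_layers = n_layers), class = "trait_params")
}

#' Extract all architecture traits from a segmented shoot cloud
#'
#' Runs [plant_height()], [projected_area()], [layered_projected_area()],
#' [leaf_area()], [convex_volume()] and [compactness()] on a calibrated,
#' shoot-only cloud. Each trait is computed independently; a failure in one
#' is recorded in the `errors` field while the rest are still reported.
#'
#' @param cloud Calibrated, segmented shoot [point_cloud()].
#' @param params A [trait_params()].
#' @return A `shoot_traits` object; see [tidy.shoot_traits()] and
#'   [glance.shoot_traits()].
#' @export
extract_traits <- function(cloud, params = trait_params()) {
  cloud <- assert_cloud(cloud)
  errors <- list()
  grab <- function(name, expr) {
    tryCatch(suppressWarnings(expr), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  height <- grab("plant_height_cm", plant_height(cloud))
  parea <- grab("projected_area_cm2",
                projected_area(cloud, params$projected_voxel_cm, params$max_edge_factor))
  layers <- tryCatch(
    suppressWarnings(layered_projected_area(cloud, params$n_layers,
                                            params$projected_voxel_cm,
                                            params$max_edge_factor)),
    error = function(e) {
      errors[["layer_projected_areas_cm2"]] <<- conditionMessage(e)
      tibble(layer = integer(), z_low_cm = numeric(), z_high_cm = numeric(),
             n_points = integer(), area_cm2 = numeric())
    })
  larea <- grab("leaf_area_cm2",
                leaf_area(cloud, params$leaf_voxel_cm, params$mls_radius_cm,
                          params$poly_order, params$max_edge_factor))
  cvol <- grab("convex_volume_cm3", convex_volume(cloud))
  comp <- grab("compactness",
               compactness(cloud, params$projected_voxel_cm, params$max_edge_factor))
  structure(list(plant_height_cm = height, projected_area_cm2 = parea,
                 layer_projected_areas_cm2 = layers,
                 leaf_area_cm2 = as.numeric(larea), convex_volume_cm3 = cvol,
                 compactness = comp, n_layers = params$n_layers,
                 n_points = nrow(cloud), parameters = params, errors = errors),
            class = "shoot_traits")
}

#' @export
print.shoot_traits <- function(x, ...) {
  cat("shoot traits:\n")
  cat(sprintf("  plant height    %8.2f cm\n", x$plant_height_cm))
  cat(sprintf("  projected area  %8.2f cm2\n", x$projected_area_cm2))
  cat(sprintf("  leaf area       %8.2f cm2\n", x$leaf_area_cm2))
  cat(sprintf("  convex volume   %8.1f cm3\n", x$convex_volume_cm3))
  cat(sprintf("  compactness     %8.3f\n", x$compactness))
  if (nrow(x$layer_projected_areas_cm2)) {
    cat(sprintf("  layer areas     %s cm2 (bottom to top)\n",
                paste(sprintf("%.1f", x$layer_projected_areas_cm2$area_cm2), collapse = ", ")))
  }
  if (length(x$errors)) {
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a shoot_traits object into a long tibble
#'
#' @param x A `shoot_traits` from [extract_traits()].
#' @param ... Unused.
#' @return Tibble with columns `trait`, `value`, `unit`.
#' @export
tidy.shoot_traits <- function(x, ...) {
  base <- tibble(
    trait = c("plant_height", "projected_area", "leaf_area", "convex_volume", "compactness"),
    value = c(x$plant_height_cm, x$projected_area_cm2, x$leaf_area_cm2,
              x$convex_volume_cm3, x$compactness),
    unit = c("cm", "cm2", "cm2", "cm3", ""))
  if (nrow(x$layer_projected_areas_cm2)) {
    base <- dplyr::bind_rows(base, tibble(
      trait = paste0("layer_area_", x$layer_projected_areas_cm2$layer),
      value = x$layer_projected_areas_cm2$area_cm2,
      unit = "cm2"))
  }
  base
}

#' Export a trait record as JSON
#'
#' Writes every trait, the per-layer areas and the full parameter echo.
#'
#' @param x A `shoot_traits` from [extract_traits()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
export_traits_json <- function(x, path) {
  stopifnot(inherits(x, "shoot_traits"))
  out <- list(
    plant_height_cm = x$plant_height_cm,
    projected_area_cm2 = x$projected_area_cm2,
    layer_projected_areas_cm2 = x$layer_projected_areas_cm2,
    leaf_area_cm2 = x$leaf_area_cm2,
    convex_volume_cm3 = x$convex_volume_cm3,
    compactness = x$compactness,
    n_points = x$n_points,
    parameters = unclass(x$parameters),
    errors = x$errors)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' One-row summary of a shoot_traits object
#'
#' @inheritParams tidy.shoot_traits
#' @return One-row tibble suitable for binding into a batch trait table.
#' @export
glance.shoot_traits <- function(x, ...) {
  out <- tibble(plant_height_cm = x$plant_height_cm,
                projected_area_cm2 = x$projected_area_cm2,
                leaf_area_cm2 = x$leaf_area_cm2,
                convex_volume_cm3 = x$convex_volume_cm3,
                compactness = x$compactness,
                n_points = x$n_points,
                n_errors = length(x$errors))
  if (nrow(x$layer_projected_areas_cm2)) {
    la <- setNames(as.list(x$layer_projected_areas_cm2$area_cm2),
                   paste0("layer_area_", x$layer_projected_areas_cm2$layer))
    out <- dplyr::bind_cols(out, as_tibble(la))
  }
  out
}
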