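#' Segment the red marker plate by an HSL color gate
#'
#' Selects exactly the points whose HSL color passes all three strict
#' inequalities `h > hue_min`, `s > sat_min`, `l > light_min`. The default
#' gate (340, 0.6, 0.3) targets the red marker plate; the hue threshold is
#' applied literally with no wrap-around union to small hues, so plates
#' should be deep red (hue above 340) rather than exactly hue 0.
#'
#' @param cloud A colored [point_cloud()].
#' @param hue_min,sat_min,light_min Gate thresholds (strict).
#' @return Integer vector of selected point indices.
#' @export
segment_plate <- function(cloud, hue_min = 340, sat_min = 0.6, light_min = 0.3) {
  cloud <- assert_cloud(cloud)
  if (!has_colors(cloud)) {
    abort("plate segmentation needs per-vertex colors; the cloud has none.")
  }
  hsl <- rgb_to_hsl(cloud$r, cloud$g, cloud$b)
  idx <- which(hsl$h > hue_min & hsl$s > sat_min & hsl$l > light_min)
  if (length(idx) == 0) {
    abort("plate not found: no points pass the color gate.")
  }
  idx
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimising orthogonal distances (smallest principal
#' direction of the centered points). The caller is responsible for
#' orienting the normal.
#'
#' @param points N x 3 matrix (N >= 10).
#' @return List with `point` (centroid), `normal` (unit), `rms_residual`
#'   and `sigma_hat` (robust MAD estimate of the out-of-plane noise).
#' @export
fit_plate_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 10) abort("plane fitting needs at least 10 points.")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300)) {
    abort("degenerate geometry: points are (near-)collinear, no unique plane.")
  }
  normal <- sv$v[, 3]
  res <- as.numeric(X %*% normal)
  list(point = ctr, normal = normal,
       rms_residual = sqrt(mean(res^2)),
       sigma_hat = mad(res, center = 0))
}

plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2, n = n)
}

#' Boundary points of the plate in its plane
#'
#' Projects the plate points into the plane's 2-D frame and returns the
#' convex-hull vertices — the detected outline of the disk.
#'
#' @param points N x 3 plate points.
#' @param plane A plane fit from [fit_plate_plane()].
#' @return M x 2 matrix of boundary points (hull order), with the plane
#'   basis attached as attributes `basis` and `origin`.
#' @export
extract_boundary <- function(points, plane) {
  points <- as.matrix(points)
  if (nrow(points) < 3) abort("boundary extraction needs at least 3 points.")
  B <- plane_basis(plane$normal)
  X <- sweep(points, 2, plane$point)
  uv <- cbind(X %*% B$e1, X %*% B$e2)
  h <- chull(uv)
  if (length(h) < 3) abort("degenerate hull: projected points are collinear.")
  structure(uv[h, , drop = FALSE], basis = B, origin = plane$point)
}

#' Least-squares circle fit
#'
#' Algebraic (Kasa) fit followed by Gauss-Newton geometric refinement of
#' `sum (|p - c| - r)^2`.
#'
#' @param points2d M x 2 matrix of boundary points.
#' @return List with `center`, `radius`, `rms_residual`.
#' @export
fit_circle <- function(points2d) {
  xy <- as.matrix(points2d)
  if (nrow(xy) < 3) abort("circle fitting needs at least 3 points.")
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  if (qr(A)$rank < 3) abort("degenerate input: collinear points have no circle.")
  sol <- qr.solve(A, x^2 + y^2)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(max(sol[3] + cx^2 + cy^2, 0))
  # geometric refinement
  for (it in 1:20) {
    dx <- x - cx; dy <- y - cy
    rho <- sqrt(dx^2 + dy^2)
    rho[rho < 1e-300] <- 1e-300
    res <- rho - r
    J <- cbind(-dx / rho, -dy / rho, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) c(0, 0, 0))
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < 1e-12 * max(r, 1)) break
  }
  rho <- sqrt((x - cx)^2 + (y - cy)^2)
  list(center = c(cx, cy), radius = r, rms_residual = sqrt(mean((rho - r)^2)))
}

## Edge-model MLE for the radius of a noise-blurred uniform disk.
## rho: in-plane distances of all plate points from the fitted centre;
## sigma: isotropic point noise; r0: initial radius estimate.
refine_disk_radius <- function(rho, sigma, r0) {
  if (sigma <= 1e-6 * r0) return(r0)
  nll <- function(r) {
    z0 <- -rho / sigma; z1 <- (r - rho) / sigma
    f <- (2 / r^2) * (rho * (stats::pnorm(z1) - stats::pnorm(z0)) +
                        sigma * (stats::dnorm(z0) - stats::dnorm(z1)))
    -sum(log(pmax(f, 1e-300)))
  }
  optimize(nll, c(0.85 * r0, 1.2 * r0))$minimum
}

#' Calibrate a raw scene to real-world units
#'
#' Finds the marker plate with [segment_plate()], fits its supporting plane
#' and outline circle ([fit_plate_plane()], [extract_boundary()],
#' [fit_circle()]), and builds the similarity transform that (i) scales the
#' scene by `real_plate_diameter_cm / estimated raw diameter`, (ii) rotates
#' the plate normal to +Z — with the sign chosen so that the side of the
#' plate with the larger point-cloud extent (the shoot side) becomes "up" —
#' and (iii) translates the plate plane to `z = plate_above_ground_cm`, so
#' the ground sits at Z = 0. The scale is applied about the plate centre.
#'
#' When `refine = TRUE` (default) the hull-circle radius is refined by a
#' maximum-likelihood fit of a noise-blurred-disk edge model to the radial
#' distribution of all plate points, using the plane fit's robust noise
#' estimate; with noisy reconstructions this removes the outward bias of a
#' convex hull drawn through the noisiest rim points.
#'
#' A plate fit whose circle RMS residual exceeds
#' `residual_warn_ratio * radius` records a warning in the result — the
#' signature of a partly occluded plate.
#'
#' @param cloud Raw colored [point_cloud()] containing the plate.
#' @param real_plate_diameter_cm True plate diameter (6 cm by default).
#' @param plate_above_ground_cm Height of the plate surface above the ground.
#' @param hue_min,sat_min,light_min Color gate, see [segment_plate()].
#' @param refine Apply the rim-model refinement.
#' @param downsample_fraction Optional random down-sampling applied before
#'   plate finding (1 = use the full cloud).
#' @param residual_warn_ratio Residual/radius ratio that triggers a warning.
#' @param seed Seed for the optional down-sampling.
#' @return List with `result` (a `plate_calibration`) and `cloud` (the
#'   calibrated [point_cloud()], `frame = "calibrated"`).
#' @export
calibrate_scene <- function(cloud, real_plate_diameter_cm = 6,
                            plate_above_ground_cm = 1, hue_min = 340,
                            sat_min = 0.6, light_min = 0.3, refine = TRUE,
                            downsample_fraction = 1, residual_warn_ratio = 0.05,
                            seed = 1L) {
  cloud <- assert_cloud(cloud)
  work <- if (downsample_fraction < 1) {
    random_downsample(cloud, downsample_fraction, seed = seed)
  } else cloud
  idx <- segment_plate(work, hue_min, sat_min, light_min)
  P <- cloud_positions(work)[idx, , drop = FALSE]
  plane <- fit_plate_plane(P)

  # orient the normal: the side with the larger extent holds the shoot
  other <- cloud_positions(work)[-idx, , drop = FALSE]
  if (nrow(other) > 10) {
    d <- as.numeric(sweep(other, 2, plane$point) %*% plane$normal)
    up <- quantile(d, 0.999); dn <- quantile(d, 0.001)
    if (abs(dn) > abs(up)) plane$normal <- -plane$normal
  }

  bnd <- extract_boundary(P, plane)
  circ <- fit_circle(bnd)
  B <- attr(bnd, "basis")
  radius_raw <- circ$radius
  warnings <- character()
  if (refine) {
    X <- sweep(P, 2, plane$point)
    uv <- cbind(X %*% B$e1, X %*% B$e2)
    rho <- sqrt((uv[, 1] - circ$center[1])^2 + (uv[, 2] - circ$center[2])^2)
    radius_raw <- refine_disk_radius(rho, plane$sigma_hat, circ$radius)
  }
  if (circ$rms_residual > residual_warn_ratio * radius_raw) {
    warnings <- c(warnings, sprintf(
      "plate fit residual %.3g exceeds %.0f%% of the radius: plate may be occluded",
      circ$rms_residual, 100 * residual_warn_ratio))
    warn(warnings[length(warnings)])
  }

  scale_factor <- real_plate_diameter_cm / (2 * radius_raw)
  Rmat <- rotation_aligning(plane$normal, c(0, 0, 1))
  center3d <- plane$point + circ$center[1] * B$e1 + circ$center[2] * B$e2
  translation <- c(0, 0, plate_above_ground_cm) -
    scale_factor * as.numeric(Rmat %*% center3d)
  transform <- similarity_transform(scale_factor, Rmat, translation)

  plate_fit <- structure(list(plane_point = plane$point, plane_normal = plane$normal,
                              center = center3d, radius = radius_raw,
                              inlier_count = length(idx),
                              rms_residual = circ$rms_residual,
                              sigma_hat = plane$sigma_hat, boundary = bnd),
                         class = "plate_fit")
  result <- structure(list(transform = transform, scale_factor = scale_factor,
                           plate_fit = plate_fit,
                           estimated_plate_diameter_raw = 2 * radius_raw,
                           real_plate_diameter_cm = real_plate_diameter_cm,
                           plate_above_ground_cm = plate_above_ground_cm,
                           warnings = warnings),
                      class = "plate_calibration")
  list(result = result, cloud = apply_transform(cloud, transform, frame = "calibrated"))
}

#' @export
print.plate_calibration <- function(x, ...) {
  cat(sprintf("plate calibration: raw radius %.5g, scale factor %.5g, residual %.3g (%d plate points)\n",
              x$plate_fit$radius, x$scale_factor, x$plate_fit$rms_residual,
              x$plate_fit$inlier_count))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' Tidy / summarise a plate calibration
#'
#' `tidy()` returns the per-quantity view (one row per reported quantity);
#' `glance()` the flat one-row report used for the calibration CSV.
#'
#' @param x A `plate_calibration` from [calibrate_scene()].
#' @param ... Unused.
#' @export
tidy.plate_calibration <- function(x, ...) {
  tibble(quantity = c("raw_plate_radius", "raw_plate_diameter", "scale_factor",
                      "rms_residual", "inlier_count", "sigma_hat"),
         value = c(x$plate_fit$radius, x$estimated_plate_diameter_raw,
                   x$scale_factor, x$plate_fit$rms_residual,
                   x$plate_fit$inlier_count, x$plate_fit$sigma_hat))
}

#' @rdname tidy.plate_calibration
#' @export
glance.plate_calibration <- function(x, ...) {
  tibble(raw_plate_radius = x$plate_fit$radius,
         scale_factor = x$scale_factor,
         rms_residual = x$plate_fit$rms_residual,
         inlier_count = x$plate_fit$inlier_count,
         sigma_hat = x$plate_fit$sigma_hat,
         n_warnings = length(x$warnings),
         warnings = paste(x$warnings, collapse = "; "))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|estimated - truth| / truth)`, plus the maximum per-item
#' percentage error.
#'
#' @param estimated,truth Equal-length numeric vectors; `truth` must be
#'   strictly positive.
#' @return One-row tibble with `mape_pct`, `max_error_pct`, `n`.
#' @export
#' @examples
#' evaluate_mape(6.06, 6)  # 1% error
evaluate_mape <- function(estimated, truth) {
  if (length(estimated) != length(truth) || length(truth) == 0) {
    abort("`estimated` and `truth` must be non-empty and of equal length.")
  }
  if (any(truth <= 0)) abort("truth values must be strictly positive.")
  ape <- 100 * abs(estimated - truth) / truth
  tibble(mape_pct = mean(ape), max_error_pct = max(ape), n = length(ape))
}
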