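#' Segmentation configuration
#'
#' Constants of the shoot-isolation pipeline. Defaults follow the
#' platform's published processing chain: a cropping cylinder at two thirds
#' of the footprint circumcircle diameter, a 10% ground cut, random
#' down-sampling to 10% of the points, and statistical denoising.
#'
#' @param cylinder_diameter_fraction Cropping cylinder diameter as a
#'   fraction of the footprint's minimum-enclosing-circle diameter.
#' @param ground_height_fraction Fraction of the Z extent removed from the
#'   bottom.
#' @param downsample_fraction Random down-sampling fraction.
#' @param pot_height_cm Pot rim height above the ground (cm).
#' @param plate_above_ground_cm Plate surface height above the ground (cm).
#' @param denoise_k Neighbors for statistical denoising.
#' @param denoise_std_ratio Standard-deviation multiplier of the denoise cut.
#' @param seed Seed for the random down-sampling stage.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(cylinder_diameter_fraction = 2 / 3,
                                ground_height_fraction = 0.10,
                                downsample_fraction = 0.10,
                                pot_height_cm = 12, plate_above_ground_cm = 1,
                                denoise_k = 50, denoise_std_ratio = 1.0,
                                seed = 1L) {
  stopifnot(cylinder_diameter_fraction > 0, cylinder_diameter_fraction <= 1,
            ground_height_fraction >= 0, ground_height_fraction < 1,
            downsample_fraction > 0, downsample_fraction <= 1,
            denoise_k >= 1, denoise_std_ratio > 0)
  structure(list(cylinder_diameter_fraction = cylinder_diameter_fraction,
                 ground_height_fraction = ground_height_fraction,
                 downsample_fraction = downsample_fraction,
                 pot_height_cm = pot_height_cm,
                 plate_above_ground_cm = plate_above_ground_cm,
                 denoise_k = as.integer(denoise_k),
                 denoise_std_ratio = denoise_std_ratio,
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

#' Crop to a vertical cylinder around the cloud's center
#'
#' The cylinder's axis passes through the centroid of the XY projection;
#' its radius is `diameter_fraction` times the radius of the minimum
#' enclosing circle of the projection. Points outside are removed —
#' the coarse cut that separates the plant region from the enclosure.
#'
#' @param cloud A [point_cloud()].
#' @param diameter_fraction Fraction of the circumcircle diameter to keep.
#' @return Filtered cloud.
#' @export
crop_cylinder <- function(cloud, diameter_fraction = 2 / 3) {
  cloud <- assert_cloud(cloud)
  if (nrow(cloud) < 3) abort("cylinder cropping needs at least 3 points.")
  xy <- cbind(cloud$x, cloud$y)
  mec <- min_enclosing_circle(xy)
  ctr <- c(mean(cloud$x), mean(cloud$y))
  keep <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2 <=
    (diameter_fraction * mec$radius)^2
  if (!any(keep)) {
    abort("cylinder crop removed every point; increase `diameter_fraction`.")
  }
  cloud_subset(cloud, keep)
}

#' Remove the lowest slice of the cloud
#'
#' Drops points with `z < z_min + height_fraction * (z_max - z_min)`
#' (strict, so points exactly at the cut height are retained).
#'
#' @param cloud A [point_cloud()].
#' @param height_fraction Fraction of the Z extent to cut from the bottom.
#' @return Filtered cloud.
#' @export
remove_ground <- function(cloud, height_fraction = 0.10) {
  cloud <- assert_cloud(cloud)
  if (nrow(cloud) < 2) abort("ground removal needs at least 2 points.")
  z0 <- min(cloud$z); z1 <- max(cloud$z)
  if (z1 - z0 <= 0) abort("zero Z extent: nothing to cut against.")
  cut <- z0 + height_fraction * (z1 - z0)
  cloud_subset(cloud, cloud$z >= cut)
}

#' Uniform random down-sampling without replacement
#'
#' Keeps exactly `round(fraction * N)` points. With a `seed` the selection
#' is reproducible and leaves the caller's RNG state untouched.
#'
#' @param cloud A [point_cloud()].
#' @param fraction Fraction of points to keep, in `(0, 1]`.
#' @param seed Optional integer seed.
#' @return Filtered cloud (row order preserved).
#' @export
random_downsample <- function(cloud, fraction = 0.10, seed = NULL) {
  cloud <- assert_cloud(cloud)
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1].")
  n <- nrow(cloud)
  keep_n <- round(fraction * n)
  idx <- if (is.null(seed)) {
    sample.int(n, keep_n)
  } else {
    withr::with_seed(as.integer(seed), sample.int(n, keep_n))
  }
  cloud_subset(cloud, sort(idx))
}

#' Remove everything at or below the pot rim
#'
#' In the calibrated frame (ground at Z = 0) the pot rim height is known,
#' so points with `z <= pot_height_cm` — ground, plate and pot — are
#' dropped, leaving the shoot candidate cloud.
#'
#' @param cloud Calibrated [point_cloud()].
#' @param pot_height_cm Pot rim height (cm).
#' @return Shoot-candidate cloud.
#' @export
crop_below_pot_edge <- function(cloud, pot_height_cm) {
  cloud <- assert_cloud(cloud)
  if (cloud_frame(cloud) != "calibrated") {
    abort("`crop_below_pot_edge` expects a calibrated cloud (ground at Z = 0).")
  }
  keep <- cloud$z > pot_height_cm
  if (!any(keep)) {
    abort("no points above the pot rim; is the pot height larger than the plant?")
  }
  cloud_subset(cloud, keep)
}

#' Statistical outlier removal
#'
#' For every point the mean distance to its `k` nearest neighbors is
#' computed; points whose mean distance exceeds the global mean plus
#' `std_ratio` standard deviations of that statistic are removed. Isolated
#' speckle clusters left by multi-view stereo matching are the target.
#'
#' @param cloud A [point_cloud()] with more than `k` points.
#' @param k Number of neighbors.
#' @param std_ratio Standard-deviation multiplier.
#' @return Denoised cloud.
#' @export
statistical_denoise <- function(cloud, k = 50, std_ratio = 1.0) {
  cloud <- assert_cloud(cloud)
  n <- nrow(cloud)
  if (n <= k) abort(sprintf("denoising needs more than k = %d points (have %d).", k, n))
  P <- cloud_positions(cloud)
  nn <- RANN::nn2(P, k = k + 1)
  md <- rowMeans(nn$nn.dists[, -1, drop = FALSE])
  thr <- mean(md) + std_ratio * sd(md)
  cloud_subset(cloud, md <= thr)
}

#' Isolate the shoot from a raw scene
#'
#' Runs the full segmentation chain: the calibration rotation is applied
#' first (so "vertical" is meaningful in an arbitrarily oriented raw
#' frame), then cylinder cropping, the ground cut and random down-sampling
#' in raw units, then the calibration scale and translation to reach the
#' calibrated frame, then the pot-rim cut and statistical denoising.
#' Per-stage point counts are attached as attribute `stage_counts` and
#' logged via `message()` unless `quiet`.
#'
#' @param cloud Raw [point_cloud()].
#' @param calibration A `plate_calibration` from [calibrate_scene()].
#' @param config A [segmentation_config()].
#' @param quiet Suppress per-stage messages.
#' @param dump_dir Optional directory: each stage's output is written there
#'   as `<stage>.ply` for debugging.
#' @return Calibrated shoot-only cloud.
#' @export
segment_shoot <- function(cloud, calibration, config = segmentation_config(),
                          quiet = TRUE, dump_dir = NULL) {
  cloud <- assert_cloud(cloud)
  stopifnot(inherits(calibration, "plate_calibration"))
  if (!is.null(dump_dir) && !dir.exists(dump_dir)) dir.create(dump_dir, recursive = TRUE)
  tf <- calibration$transform
  stage_no <- 0L
  stage <- function(name, expr) {
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("segmentation stage '%s' failed: %s", name, conditionMessage(e)))
      }),
      message = function(m) invokeRestart("muffleMessage"))
    if (!quiet) inform(sprintf("  %-18s %d points", name, nrow(out)))
    if (!is.null(dump_dir)) {
      stage_no <<- stage_no + 1L
      save_point_cloud(out, file.path(dump_dir, sprintf("%02d_%s.ply", stage_no, name)))
    }
    out
  }
  counts <- c(input = nrow(cloud))
  # orientation only (raw units, plate plane horizontal)
  orient <- similarity_transform(1, tf$rotation, c(0, 0, 0))
  out <- stage("orient", apply_transform(cloud, orient))
  out <- stage("crop_cylinder", crop_cylinder(out, config$cylinder_diameter_fraction))
  counts["crop_cylinder"] <- nrow(out)
  out <- stage("remove_ground", remove_ground(out, config$ground_height_fraction))
  counts["remove_ground"] <- nrow(out)
  out <- stage("random_downsample",
               random_downsample(out, config$downsample_fraction, seed = config$seed))
  counts["random_downsample"] <- nrow(out)
  # remaining scale + translation: full calibration relative to the rotation
  rest <- compose_transforms(tf, invert_transform(orient))
  out <- stage("calibrate", apply_transform(out, rest, frame = "calibrated"))
  out <- stage("crop_below_pot_edge", crop_below_pot_edge(out, config$pot_height_cm))
  counts["crop_below_pot_edge"] <- nrow(out)
  out <- stage("statistical_denoise",
               statistical_denoise(out, config$denoise_k, config$denoise_std_ratio))
  counts["statistical_denoise"] <- nrow(out)
  attr(out, "stage_counts") <- counts
  out
}
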