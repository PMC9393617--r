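# Shared fixtures: moderate-density scenes are cached per session so several
# test files can reuse them without regenerating.

.scene_cache <- new.env(parent = emptyenv())

test_scene <- function(seed = 11, density = 100, height = 40, tillers = 4,
                       truth_layers = FALSE, ...) {
  key <- paste(seed, density, height, tillers, truth_layers, ...)
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  sp <- scene_spec(seed = seed, points_per_cm2 = density,
                   shoot = shoot_spec(shoot_height_cm = height,
                                      tiller_count = tillers), ...)
  sc <- generate_scene(sp, truth_layers = truth_layers)
  .scene_cache[[key]] <- sc
  sc
}

test_calibrated_shoot <- function(seed = 11, density = 100, height = 40,
                                  tillers = 4, ...) {
  key <- paste("shoot", seed, density, height, tillers, ...)
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  sc <- test_scene(seed, density, height, tillers, ...)
  cal <- calibrate_scene(sc$cloud)
  shoot <- segment_shoot(sc$cloud, cal$result)
  out <- list(scene = sc, cal = cal, shoot = shoot)
  .scene_cache[[key]] <- out
  out
}

# segmentation audit at default density: run the chain up to the denoise
# stage and measure speckle removal vs shoot loss from the component labels
denoise_audit <- function(seed = 68) {
  key <- paste("denoise", seed)
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  sc <- generate_scene(scene_spec(seed = seed))
  cal <- calibrate_scene(sc$cloud)
  cfg <- segmentation_config()
  orient <- similarity_transform(1, cal$result$transform$rotation, c(0, 0, 0))
  out <- apply_transform(sc$cloud, orient)
  out <- crop_cylinder(out, cfg$cylinder_diameter_fraction)
  out <- remove_ground(out, cfg$ground_height_fraction)
  out <- random_downsample(out, cfg$downsample_fraction, seed = cfg$seed)
  rest <- compose_transforms(cal$result$transform, invert_transform(orient))
  out <- apply_transform(out, rest, frame = "calibrated")
  out <- crop_below_pot_edge(out, cfg$pot_height_cm)
  den <- statistical_denoise(out, cfg$denoise_k, cfg$denoise_std_ratio)
  res <- list(
    removal = 1 - sum(den$component == "outlier") / sum(out$component == "outlier"),
    shoot_loss = 1 - sum(den$component == "shoot") / sum(out$component == "shoot"))
  .scene_cache[[key]] <- res
  res
}

# dense uniform samples of simple shapes
sample_disk <- function(n, r = 1, z = NULL) {
  rho <- r * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  xy <- cbind(rho * cos(th), rho * sin(th))
  if (is.null(z)) xy else cbind(xy, z)
}

sample_rect <- function(n, w, h, z = 0) {
  cbind(runif(n, 0, w), runif(n, 0, h), z)
}
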