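#' Pipeline run configuration
#'
#' Bundles every tunable of the calibrate - segment - extract chain.
#' Defaults mirror the platform's published constants: a 6 cm plate,
#' two-thirds cropping cylinder, 10% ground cut, 10% random down-sampling
#' and an order-3 smoothing polynomial.
#'
#' @param real_plate_diameter_cm True marker plate diameter.
#' @param segmentation A [segmentation_config()].
#' @param traits A [trait_params()].
#' @param calibration_downsample Down-sampling fraction used during plate
#'   finding only (1 = full cloud).
#' @param refine_plate Use the rim-model radius refinement.
#' @param seed Master seed (also used for segmentation when its config
#'   does not override it).
#' @param quiet Suppress stage logging.
#' @return A `run_config` list.
#' @export
run_config <- function(real_plate_diameter_cm = 6,
                       segmentation = segmentation_config(),
                       traits = trait_params(), calibration_downsample = 1,
                       refine_plate = TRUE, seed = 1L, quiet = TRUE) {
  structure(list(real_plate_diameter_cm = real_plate_diameter_cm,
                 segmentation = segmentation, traits = traits,
                 calibration_downsample = calibration_downsample,
                 refine_plate = refine_plate, seed = as.integer(seed),
                 quiet = quiet),
            class = "run_config")
}

#' Run the full pipeline on one cloud
#'
#' Loads the cloud (if given a path), calibrates it from the marker plate,
#' segments the shoot and extracts the trait record. On calibration or
#' segmentation failure a structured error record is returned instead of
#' raising, so batch runs keep going.
#'
#' @param input A file path or a [point_cloud()].
#' @param config A [run_config()].
#' @param sample_id Identifier for the output row; defaults to the file
#'   stem (or `"cloud"` for in-memory input).
#' @param out_dir Optional directory: appends the trait row to
#'   `traits.csv` and the calibration report to `calibration.csv`.
#' @return A `pipeline_run` list: `sample_id`, `ok`, `traits`,
#'   `calibration`, `shoot_cloud`, `error`.
#' @export
run_single <- function(input, config = run_config(), sample_id = NULL,
                       out_dir = NULL) {
  if (is.character(input)) {
    sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(input))
  } else {
    sample_id <- sample_id %||% "cloud"
  }
  res <- tryCatch({
    cloud <- if (is.character(input)) load_point_cloud(input) else assert_cloud(input)
    cal <- suppressWarnings(calibrate_scene(
      cloud, real_plate_diameter_cm = config$real_plate_diameter_cm,
      plate_above_ground_cm = config$segmentation$plate_above_ground_cm,
      refine = config$refine_plate,
      downsample_fraction = config$calibration_downsample,
      seed = config$seed))
    shoot <- segment_shoot(cloud, cal$result, config$segmentation,
                           quiet = config$quiet)
    traits <- extract_traits(shoot, config$traits)
    list(ok = TRUE, calibration = cal$result, shoot_cloud = shoot,
         traits = traits, error = NULL)
  }, error = function(e) {
    list(ok = FALSE, calibration = NULL, shoot_cloud = NULL, traits = NULL,
         error = conditionMessage(e))
  })
  run <- structure(c(list(sample_id = sample_id), res), class = "pipeline_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline run '%s': %s\n", x$sample_id,
              if (x$ok) "ok" else paste("FAILED -", x$error)))
  if (x$ok) print(x$traits)
  invisible(x)
}

#' One-row table for a pipeline run
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return One-row tibble; failed runs carry their error message and NA
#'   traits.
#' @export
glance.pipeline_run <- function(x, ...) {
  if (!x$ok) {
    return(tibble(sample_id = x$sample_id, ok = FALSE, error = x$error))
  }
  dplyr::bind_cols(
    tibble(sample_id = x$sample_id, ok = TRUE, error = NA_character_),
    glance(x$traits),
    dplyr::rename_with(glance(x$calibration), ~ paste0("cal_", .x)))
}

write_run_outputs <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  row <- glance(run)
  tpath <- file.path(out_dir, "traits.csv")
  readr::write_csv(row, tpath, append = file.exists(tpath))
  if (run$ok) {
    cpath <- file.path(out_dir, "calibration.csv")
    crow <- dplyr::bind_cols(tibble(sample_id = run$sample_id),
                             glance(run$calibration))
    readr::write_csv(crow, cpath, append = file.exists(cpath))
  }
  invisible(run)
}

#' Run the pipeline over a batch of clouds
#'
#' @param inputs A directory (all `.ply`/`.xyz`/`.txt` files), a glob, or a
#'   character vector of paths.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for `traits.csv` /
#'   `calibration.csv`.
#' @return A tibble with one row per input file; failures become rows with
#'   `ok = FALSE` and the error message, never lost rows.
#' @export
run_batch <- function(inputs, config = run_config(), out_dir = NULL) {
  paths <- resolve_inputs(inputs)
  if (length(paths) == 0) abort("no input clouds matched.")
  runs <- purrr::map(paths, function(p) {
    run_single(p, config = config, out_dir = out_dir)
  })
  tab <- purrr::map_dfr(runs, glance)
  n_ok <- sum(tab$ok)
  if (!is.null(out_dir)) {
    manifest <- list(inputs = paths, n_ok = n_ok, n_failed = nrow(tab) - n_ok,
                     real_plate_diameter_cm = config$real_plate_diameter_cm,
                     segmentation = unclass(config$segmentation),
                     traits = unclass(config$traits), seed = config$seed)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  inform(sprintf("batch: %d/%d clouds processed successfully.", n_ok, nrow(tab)))
  tab
}

resolve_inputs <- function(inputs) {
  if (length(inputs) == 1 && dir.exists(inputs)) {
    return(sort(list.files(inputs, pattern = "\\.(ply|xyz|txt|xyzrgb)$",
                           full.names = TRUE, ignore.case = TRUE)))
  }
  if (length(inputs) == 1 && grepl("[*?]", inputs)) {
    return(sort(Sys.glob(inputs)))
  }
  inputs[file.exists(inputs)]
}

#' Write a set of synthetic scenes plus their truth table
#'
#' Drives [generate_scene()] `n` times with per-scene seeds derived from
#' `seed`, writes `scene_<i>.ply` files and a `truth.csv` sidecar.
#'
#' @param out_dir Output directory (created if missing).
#' @param n Number of scenes.
#' @param spec Base [scene_spec()]; per-scene seed and (optionally) scale
#'   are overridden.
#' @param seed Master seed.
#' @param scale_sweep If `TRUE`, applied scales are spaced log-uniformly so
#'   raw plate radii sweep the 0.02-0.2 scene-unit regime.
#' @param occlude_plate Generate the plate-occlusion failure mode.
#' @return Invisibly, a tibble of file paths and scene truths.
#' @export
make_scenes <- function(out_dir, n = 3, spec = scene_spec(), seed = 1L,
                        scale_sweep = FALSE, occlude_plate = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  scales <- if (scale_sweep) {
    exp(seq(log(0.02 / spec$plate_radius_cm), log(0.2 / spec$plate_radius_cm),
            length.out = n))
  } else rep(list(NULL), n)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- as.integer(seed * 1000 + i)
    sp$occlude_plate <- occlude_plate
    if (scale_sweep) sp$applied_scale <- scales[[i]]
    sc <- generate_scene(sp)
    path <- file.path(out_dir, sprintf("scene_%03d.ply", i))
    save_point_cloud(sc$cloud, path)
    dplyr::bind_cols(tibble(sample_id = sprintf("scene_%03d", i), path = path),
                     glance(sc$truth))
  })
  readr::write_csv(rows, file.path(out_dir, "truth.csv"))
  invisible(rows)
}
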