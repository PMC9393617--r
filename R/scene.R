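#' Specify a synthetic multi-tiller shoot
#'
#' Parameters of the simulated wheat-like shoot: a handful of tillers, each
#' a thin stem carrying several narrow arched leaf blades. Fields left
#' `NULL` are drawn from the stated ranges inside [generate_scene()] so
#' that every scene seed yields a different plant.
#'
#' @param tiller_count Number of tillers (drawn from 2..10 when `NULL`).
#' @param leaves_per_tiller Leaves on each tiller (drawn from 3..6 when `NULL`).
#' @param leaf_length_range Blade length range in cm.
#' @param leaf_width_range Blade max-width range in cm.
#' @param shoot_height_cm Target plant height above the soil surface, cm
#'   (drawn from `[10, 80]` when `NULL`). The generated shoot is scaled
#'   isotropically about the soil surface to hit this height exactly.
#' @param tiller_spread_deg Maximum tilt of tiller stems from the vertical.
#' @return A `shoot_spec` list.
#' @export
shoot_spec <- function(tiller_count = NULL, leaves_per_tiller = NULL,
                       leaf_length_range = c(5, 25), leaf_width_range = c(0.5, 2.5),
                       shoot_height_cm = NULL, tiller_spread_deg = 25) {
  stopifnot(length(leaf_length_range) == 2, length(leaf_width_range) == 2,
            all(leaf_length_range > 0), all(leaf_width_range > 0),
            diff(leaf_length_range) >= 0, diff(leaf_width_range) >= 0)
  if (!is.null(shoot_height_cm) && shoot_height_cm <= 0) abort("`shoot_height_cm` must be positive.")
  structure(list(tiller_count = tiller_count, leaves_per_tiller = leaves_per_tiller,
                 leaf_length_range = leaf_length_range, leaf_width_range = leaf_width_range,
                 shoot_height_cm = shoot_height_cm, tiller_spread_deg = tiller_spread_deg),
            class = "shoot_spec")
}

#' Specify a synthetic reconstruction scene
#'
#' Describes the interior of the imaging chamber as the reconstruction sees
#' it: a circular ground sheet, a pot with a soil surface, a red marker
#' plate of known radius raised slightly above the ground, and a shoot
#' rooted in the pot. The assembled scene is mapped through an unknown
#' similarity transform (the reconstruction's arbitrary scale, orientation
#' and position), then perturbed with isotropic Gaussian point noise and a
#' few sparse outlier clusters, emulating multi-view-stereo output.
#'
#' The default `applied_scale = NULL` draws the scale log-uniformly so that
#' the raw (scene-unit) plate radius lands in `[0.02, 0.2]` for the default
#' 3 cm plate, matching the regime observed in real reconstructions.
#'
#' @param plate_radius_cm True marker plate radius (cm).
#' @param plate_center_offset_cm Length-2 ground-plane offset of the plate
#'   centre from the pot axis.
#' @param plate_hue_deg Plate hue in degrees; must satisfy the segmentation
#'   gate, i.e. lie in `(340, 360)`.
#' @param pot_height_cm,pot_radius_cm Pot shell dimensions.
#' @param plate_above_ground_cm Height of the plate surface above the ground.
#' @param ground_radius_cm Radius of the visible ground sheet.
#' @param shoot A [shoot_spec()].
#' @param applied_scale Similarity scale applied to the scene (`NULL` =
#'   draw log-uniformly from `[0.02, 0.2] / plate_radius_cm`).
#' @param applied_rotation 3 x 3 rotation applied to the scene (`NULL` =
#'   random rotation).
#' @param noise_sigma_cm Isotropic point noise, cm in real units (applied as
#'   `noise_sigma_cm * applied_scale` after scaling).
#' @param outlier_fraction Fraction of points added as sparse speckle
#'   clusters, in `[0, 0.05]`.
#' @param points_per_cm2 Surface sampling density.
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   the spec.
#' @param occlude_plate If `TRUE`, removes a sector of the plate and drapes
#'   leaf points over it, emulating the plate-occlusion failure mode.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(plate_radius_cm = 3, plate_center_offset_cm = c(13, 0),
                       plate_hue_deg = 350, pot_height_cm = 12, pot_radius_cm = 6.5,
                       plate_above_ground_cm = 1, ground_radius_cm = 24,
                       shoot = shoot_spec(), applied_scale = NULL,
                       applied_rotation = NULL, noise_sigma_cm = 0.02,
                       outlier_fraction = 0.01, points_per_cm2 = 500, seed = 1,
                       occlude_plate = FALSE) {
  spec <- structure(list(plate_radius_cm = plate_radius_cm,
                         plate_center_offset_cm = plate_center_offset_cm,
                         plate_hue_deg = plate_hue_deg, pot_height_cm = pot_height_cm,
                         pot_radius_cm = pot_radius_cm,
                         plate_above_ground_cm = plate_above_ground_cm,
                         ground_radius_cm = ground_radius_cm, shoot = shoot,
                         applied_scale = applied_scale, applied_rotation = applied_rotation,
                         noise_sigma_cm = noise_sigma_cm, outlier_fraction = outlier_fraction,
                         points_per_cm2 = points_per_cm2, seed = as.integer(seed),
                         occlude_plate = occlude_plate),
                    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (plate_radius_cm <= 0) abort("plate radius must be positive.")
    if (!(plate_hue_deg > 340 && plate_hue_deg < 360)) {
      abort("`plate_hue_deg` must lie in (340, 360) so the plate passes the color gate.")
    }
    if (!is.null(applied_scale) && applied_scale <= 0) abort("`applied_scale` must be positive.")
    if (points_per_cm2 <= 0) abort("`points_per_cm2` must be positive.")
    if (noise_sigma_cm < 0) abort("`noise_sigma_cm` must be non-negative.")
    if (outlier_fraction < 0 || outlier_fraction > 0.05) {
      abort("`outlier_fraction` must lie in [0, 0.05].")
    }
    d <- sqrt(sum(plate_center_offset_cm^2))
    if (d - plate_radius_cm <= pot_radius_cm) {
      abort("plate overlaps the pot footprint; move `plate_center_offset_cm` outward.")
    }
    if (d + plate_radius_cm > ground_radius_cm) {
      abort("plate extends beyond the ground sheet.")
    }
    if (plate_above_ground_cm >= pot_height_cm) {
      abort("plate must sit below the pot rim.")
    }
    if (!is.null(applied_rotation)) check_rotation(applied_rotation)
  })
  invisible(spec)
}

uniform_disk <- function(n, radius) {
  rho <- radius * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  cbind(rho * cos(th), rho * sin(th))
}

jitter_hsl_colors <- function(n, h, s, l, dh = 2, ds = 0.05, dl = 0.02) {
  hsl_to_rgb(h + runif(n, -dh, dh),
             pmin(pmax(s + runif(n, -ds, ds), 0), 1),
             pmin(pmax(l + runif(n, -dl, dl), 0), 1))
}

#' Generate a ground-truthed synthetic scene
#'
#' Assembles the scene described by a [scene_spec()], applies the unknown
#' similarity transform and noise, and returns both the raw colored cloud
#' (as a reconstruction would deliver it) and the ground truth needed to
#' score the pipeline. The cloud carries a `component` label column
#' (`ground`, `pot`, `plate`, `shoot`, `outlier`) which the processing
#' stages simply pass through, so segmentation accuracy can be audited.
#'
#' Ground truth is recorded in the pre-transform real-unit frame:
#' `height_cm` is the shoot's vertical extent above the soil surface
#' (i.e. `max z - soil z` of the clean shoot points, the quantity plant
#' height measures), `leaf_area_cm2` the analytic sum of single-sided blade
#' areas, and `plate_radius_cm` the specified plate radius. With
#' `truth_layers = TRUE` the per-layer and total projected areas of the
#' clean shoot are measured by converged fine-scale meshing (0.05 cm
#' voxels) and stored as well.
#'
#' @param spec A [scene_spec()].
#' @param truth_layers Also compute projected-area ground truth (slower).
#' @param n_layers Number of equal-height layers for the layer truth.
#' @return A list with elements `cloud` (a raw-frame [point_cloud()]) and
#'   `truth` (a `scene_truth` list; see [glance.scene_truth()]).
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(seed = 7, points_per_cm2 = 30))
#' sc$truth$height_cm
generate_scene <- function(spec, truth_layers = FALSE, n_layers = 4) {
  validate_scene_spec(spec)
  withr::with_seed(spec$seed, generate_scene_impl(spec, truth_layers, n_layers))
}

generate_scene_impl <- function(spec, truth_layers, n_layers) {
  dens <- spec$points_per_cm2
  # soil surface sits slightly recessed below the pot rim, as in a real pot
  soil_z <- spec$pot_height_cm - 0.2

  ## ---- shoot (built in a soil frame, z = 0 at the soil surface) --------
  ## blades must stay inside the 2/3 cropping cylinder, as the platform's
  ## enclosure guarantees for real plants
  shoot <- build_shoot(spec$shoot, dens,
                       max_reach_cm = 0.95 * (2 / 3) * spec$ground_radius_cm)
  shoot_pts <- shoot$points
  shoot_pts[, 3] <- shoot_pts[, 3] + soil_z

  ## ---- ground sheet (avoid the pot footprint and the plate shadow) -----
  g_area <- pi * spec$ground_radius_cm^2
  n_g <- round(g_area * dens)
  g <- uniform_disk(n_g, spec$ground_radius_cm)
  off <- spec$plate_center_offset_cm
  hide <- sqrt(g[, 1]^2 + g[, 2]^2) < spec$pot_radius_cm |
    sqrt((g[, 1] - off[1])^2 + (g[, 2] - off[2])^2) < spec$plate_radius_cm
  g <- g[!hide, , drop = FALSE]
  ground_pts <- cbind(g, 0)

  ## ---- pot: shell plus soil disk ---------------------------------------
  n_side <- round(2 * pi * spec$pot_radius_cm * spec$pot_height_cm * dens)
  th <- runif(n_side, 0, 2 * pi)
  zz <- runif(n_side, 0, spec$pot_height_cm)
  side <- cbind(spec$pot_radius_cm * cos(th), spec$pot_radius_cm * sin(th), zz)
  n_soil <- round(pi * spec$pot_radius_cm^2 * dens)
  soil <- cbind(uniform_disk(n_soil, spec$pot_radius_cm * 0.98), soil_z)
  pot_pts <- rbind(side, soil)

  ## ---- marker plate -----------------------------------------------------
  n_p <- round(pi * spec$plate_radius_cm^2 * dens)
  pd <- uniform_disk(n_p, spec$plate_radius_cm)
  plate_pts <- cbind(pd[, 1] + off[1], pd[, 2] + off[2], spec$plate_above_ground_cm)
  if (spec$occlude_plate) {
    # leaves draped across one side of the plate hide everything beyond a
    # chord, so the detected boundary is an arc plus a straight edge
    bite <- pd[, 1] > 0.25 * spec$plate_radius_cm
    occl <- uniform_disk(round(sum(bite) * 0.6), spec$plate_radius_cm * 0.8)
    occl <- cbind(occl[, 1] + off[1] + 0.5, occl[, 2] + off[2],
                  spec$plate_above_ground_cm + runif(nrow(occl), 0.05, 0.4))
    plate_pts <- plate_pts[!bite, , drop = FALSE]
    shoot_pts <- rbind(shoot_pts, occl)
  }

  ## ---- colors, assigned in HSL so the plate passes its gate -------------
  col_ground <- jitter_hsl_colors(nrow(ground_pts), 30, 0.12, 0.35)
  col_pot <- jitter_hsl_colors(nrow(pot_pts), 210, 0.25, 0.40)
  col_plate <- jitter_hsl_colors(nrow(plate_pts), spec$plate_hue_deg, 0.80, 0.48,
                                 dh = min(2, 359.5 - spec$plate_hue_deg,
                                          spec$plate_hue_deg - 340.5),
                                 ds = 0.05, dl = 0.05)
  col_shoot <- jitter_hsl_colors(nrow(shoot_pts), 115, 0.55, 0.32, dh = 12, ds = 0.1, dl = 0.06)

  P <- rbind(ground_pts, pot_pts, plate_pts, shoot_pts)
  colors <- as.matrix(dplyr::bind_rows(col_ground, col_pot, col_plate, col_shoot))
  component <- rep(c("ground", "pot", "plate", "shoot"),
                   c(nrow(ground_pts), nrow(pot_pts), nrow(plate_pts), nrow(shoot_pts)))

  ## ---- outlier speckle clusters ----------------------------------------
  n_out <- round(spec$outlier_fraction * nrow(P))
  if (n_out > 0) {
    # diffuse speckle clusters, each well below the denoiser's neighborhood
    # size even where two overlap
    n_cl <- max(1L, ceiling(n_out / 30))
    lo <- apply(P, 2, min); hi <- apply(P, 2, max)
    centers <- cbind(runif(n_cl, lo[1], hi[1]), runif(n_cl, lo[2], hi[2]),
                     runif(n_cl, lo[3], hi[3] + 5))
    assign_cl <- sample.int(n_cl, n_out, replace = TRUE)
    out_pts <- centers[assign_cl, , drop = FALSE] + matrix(rnorm(3 * n_out, 0, 1.2), ncol = 3)
    P <- rbind(P, out_pts)
    colors <- rbind(colors, as.matrix(jitter_hsl_colors(n_out, 60, 0.1, 0.5, dh = 30)))
    component <- c(component, rep("outlier", n_out))
  }

  ## ---- ground truth (pre-transform, real units) -------------------------
  sh_idx <- component == "shoot"
  truth <- structure(list(
    applied_scale = NA_real_,
    height_cm = max(P[sh_idx, 3]) - soil_z,
    leaf_area_cm2 = shoot$leaf_area_cm2,
    plate_radius_cm = spec$plate_radius_cm,
    soil_z_cm = soil_z,
    point_counts = table(component),
    layer_projected_area_cm2 = NULL,
    projected_area_cm2 = NA_real_,
    seed = spec$seed
  ), class = "scene_truth")
  if (truth_layers) {
    sp <- P[sh_idx, , drop = FALSE]
    la <- layered_projected_area(point_cloud(sp, frame = "calibrated"),
                                 n_layers = n_layers, voxel_size_cm = 0.05)
    truth$layer_projected_area_cm2 <- la$area_cm2
    truth$projected_area_cm2 <- projected_area(point_cloud(sp, frame = "calibrated"),
                                               voxel_size_cm = 0.05)
  }

  ## ---- the unknown similarity transform + noise -------------------------
  s_appl <- spec$applied_scale %||%
    exp(runif(1, log(0.02 / spec$plate_radius_cm), log(0.2 / spec$plate_radius_cm)))
  R_appl <- spec$applied_rotation %||% random_rotation()
  t_appl <- runif(3, -5, 5) * s_appl
  truth$applied_scale <- s_appl
  tf <- similarity_transform(s_appl, R_appl, t_appl)
  P <- s_appl * (P %*% t(R_appl))
  P <- sweep(P, 2, t_appl, "+")
  if (spec$noise_sigma_cm > 0) {
    P <- P + matrix(rnorm(length(P), 0, spec$noise_sigma_cm * s_appl), ncol = 3)
  }
  truth$applied_transform <- tf

  cloud <- point_cloud(P, colors = colors, frame = "raw", component = component)
  list(cloud = cloud, truth = truth)
}

## horizontal excursion of a circular-arc midrib of arc length L whose
## inclination falls linearly from elev to tip (degrees)
blade_reach <- function(L, elev_deg, tip_deg) {
  p0 <- elev_deg * pi / 180; p1 <- tip_deg * pi / 180
  if (abs(p0 - p1) < 1e-9) return(L * cos(p0))
  L * (sin(p0) - sin(p1)) / (p0 - p1)
}

## lays out tillers and leaves for a target height, then rescales the shoot
## isotropically about the soil surface so the tallest point hits it exactly
build_shoot <- function(sh, dens, max_reach_cm = Inf) {
  tn <- sh$tiller_count %||% sample(2:10, 1)
  nl <- sh$leaves_per_tiller %||% sample(3:6, 1)
  H <- sh$shoot_height_cm %||% runif(1, 10, 80)
  lr <- sh$leaf_length_range; wr <- sh$leaf_width_range

  leaves <- list(); stems <- list()
  for (i in seq_len(tn)) {
    az <- runif(1, 0, 2 * pi)
    tilt <- sh$tiller_spread_deg * runif(1, 0.2, 1) * pi / 180
    b_off <- uniform_disk(1, 1.2)
    hs <- H * runif(1, 0.55, 0.75)
    # tall tillers stand upright: cap the stem top's horizontal excursion
    tilt <- min(tilt, asin(min(1, 6 / hs)))
    dir <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))
    base <- c(b_off[1], b_off[2], 0)
    top <- base + hs * dir
    stems[[i]] <- list(base = base, top = top, len = hs)
    lo <- max(lr[1], 0.25 * H); hi <- min(lr[2], max(0.45 * H + 4, lr[1] + 0.5))
    if (hi <= lo) hi <- lo + 0.5
    for (j in seq_len(nl)) {
      fj <- j / nl
      node <- base + (0.25 + 0.72 * fj) * hs * dir
      L <- min(runif(1, lo, hi) * (0.75 + 0.35 * fj), lr[2])
      W <- runif(1, wr[1], wr[2])
      W <- min(W, 0.45 * L)
      leaves[[length(leaves) + 1]] <- list(
        base = node, L = L, W = W,
        yaw = (az + runif(1, -0.8, 0.8)) * 180 / pi,
        elev = 35 + 40 * fj + runif(1, -8, 8),
        tip = runif(1, -45, 0))
    }
  }
  apex_and_scale <- function() {
    # natural apex from the parametric midribs (cheap, no sampling)
    apex <- max(vapply(stems, function(s) s$top[3], 0))
    for (lf in leaves) {
      geom <- leaf_midrib(lf$L, lf$base, lf$yaw, lf$elev, lf$tip, 100)
      apex <- max(apex, max(geom$m[, 3]))
    }
    H / apex
  }
  # keep every blade inside the cropping fence: steepen over-reaching
  # blades, shorten those that still overshoot (two passes, since the
  # height-normalising scale shifts when blades steepen)
  s <- apex_and_scale()
  if (is.finite(max_reach_cm)) {
    for (pass in 1:2) {
      for (k in seq_along(leaves)) {
        lf <- leaves[[k]]
        node_r <- sqrt(lf$base[1]^2 + lf$base[2]^2)
        budget <- max_reach_cm / s - node_r
        while (blade_reach(lf$L, lf$elev, lf$tip) > budget && lf$elev < 83) {
          lf$elev <- lf$elev + 4
        }
        reach <- blade_reach(lf$L, lf$elev, lf$tip)
        if (reach > budget && budget > 1) {
          lf$L <- lf$L * budget / reach
          lf$W <- min(lf$W, 0.45 * lf$L)
        }
        leaves[[k]] <- lf
      }
      s <- apex_and_scale()
    }
  }

  pts <- list(); area <- 0
  for (st in stems) {
    n <- max(2L, round(2 * pi * 0.15 * st$len * s^2 * dens))
    tt <- runif(n); th <- runif(n, 0, 2 * pi)
    ax <- st$top - st$base
    # crude orthonormal frame around the stem axis
    e1 <- c(-ax[2], ax[1], 0); if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    e2 <- e2 / sqrt(sum(e2^2))
    p <- matrix(st$base, n, 3, byrow = TRUE) + outer(tt, ax) +
      0.15 * (outer(cos(th), e1) + outer(sin(th), e2))
    pts[[length(pts) + 1]] <- p
  }
  for (lf in leaves) {
    out <- generate_leaf(lf$L * s, lf$W * s, base = lf$base * s, yaw_deg = lf$yaw,
                         elev_deg = lf$elev, tip_angle_deg = lf$tip,
                         density_per_cm2 = dens)
    # leaf sampled at final size but base already scaled: rescale positions
    # of stem-frame geometry uniformly about the soil origin
    pts[[length(pts) + 1]] <- out$points
    area <- area + out$area_cm2
  }
  P <- do.call(rbind, pts)
  # stems were laid out in natural units; scale them about the origin
  ns <- sum(vapply(stems, function(st) max(2, round(2 * pi * 0.15 * st$len * s^2 * dens)), 0))
  P[seq_len(ns), ] <- P[seq_len(ns), , drop = FALSE] * s
  list(points = P, leaf_area_cm2 = area, tiller_count = tn, height_cm = H)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene truth: height %.2f cm, leaf area %.1f cm2, plate r %.2f cm, scale %.4g\n",
              x$height_cm, x$leaf_area_cm2, x$plate_radius_cm, x$applied_scale))
  invisible(x)
}

#' Flatten scene ground truth to a one-row tibble
#'
#' @param x A `scene_truth` from [generate_scene()].
#' @param ... Unused.
#' @return One-row tibble (layer areas as `layer_area_1..k` when present).
#' @export
glance.scene_truth <- function(x, ...) {
  out <- tibble(seed = x$seed, applied_scale = x$applied_scale,
                height_cm = x$height_cm, leaf_area_cm2 = x$leaf_area_cm2,
                plate_radius_cm = x$plate_radius_cm,
                projected_area_cm2 = x$projected_area_cm2,
                n_shoot = as.integer(x$point_counts["shoot"]),
                n_plate = as.integer(x$point_counts["plate"]))
  if (!is.null(x$layer_projected_area_cm2)) {
    la <- setNames(as.list(x$layer_projected_area_cm2),
                   paste0("layer_area_", seq_along(x$layer_projected_area_cm2)))
    out <- dplyr::bind_cols(out, as_tibble(la))
  }
  out
}
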