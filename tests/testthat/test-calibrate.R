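test_that("the plate color gate applies strict inequalities", {
  mk <- function(h, s, l) {
    rgb <- hsl_to_rgb(h, s, l)
    point_cloud(matrix(0, length(h), 3), colors = as.matrix(rgb))
  }
  sel <- segment_plate(mk(c(350, 120, 345), c(0.8, 0.9, 0.7), c(0.5, 0.5, 0.5)))
  expect_equal(sel, c(1L, 3L))
  # exact boundary values fail all-strict gating
  expect_error(segment_plate(mk(340, 0.6, 0.3)), "plate not found")
  expect_error(segment_plate(point_cloud(matrix(0, 5, 3))), "colors")
})

test_that("plane fitting recovers exact, tilted and noisy planes", {
  set.seed(31)
  flat <- cbind(runif(200), runif(200), 0.3)
  pl <- fit_plate_plane(flat)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$point[3], 0.3, tolerance = 1e-12)

  R <- rotation_about_axis(c(1, 2, 0), 35)
  disk <- sample_disk(4000, 3, 0)
  tilted <- disk %*% t(R)
  pl2 <- fit_plate_plane(tilted)
  ang <- acos(min(1, abs(sum(pl2$normal * R[, 3])))) * 180 / pi
  expect_lt(ang, 0.1)

  noisy <- tilted + matrix(rnorm(nrow(tilted) * 3, 0, 0.03), ncol = 3)
  pl3 <- fit_plate_plane(noisy)
  ang3 <- acos(min(1, abs(sum(pl3$normal * R[, 3])))) * 180 / pi
  expect_lt(ang3, 1)
  # sigma_hat tracks the injected noise
  expect_equal(pl3$sigma_hat, 0.03, tolerance = 0.3)

  line <- cbind(1:20, 2 * (1:20), 3 * (1:20))
  expect_error(fit_plate_plane(line), "collinear")
})

test_that("boundary extraction returns the hull in the plane frame", {
  set.seed(32)
  disk <- sample_disk(5000, 1, 0)
  pl <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  bnd <- extract_boundary(disk, pl)
  rad <- sqrt(rowSums(bnd^2))
  expect_gt(min(rad), 0.97)
  expect_lte(max(rad), 1)

  sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  expect_equal(nrow(extract_boundary(sq, pl)), 4)
  expect_error(extract_boundary(cbind(1:5, 1:5, 0), pl), "collinear")
  expect_error(extract_boundary(sq[1:2, ], pl), "3 points")
})

test_that("circle fitting matches closed-form cases and recovers noisy circles", {
  tri <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  f <- fit_circle(tri)
  expect_equal(f$center, c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(f$radius, 1, tolerance = 1e-9)

  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  expect_equal(fit_circle(sq)$radius, sqrt(2), tolerance = 1e-9)

  set.seed(33)
  th <- runif(200, 0, 2 * pi)
  pts <- cbind(3 * cos(th), 3 * sin(th)) * (1 + rnorm(200, 0, 0.005))
  expect_equal(fit_circle(pts)$radius, 3, tolerance = 0.015)

  expect_error(fit_circle(cbind(1:5, 1:5)), "collinear")
})

test_that("calibration recovers the applied scale and uprights the scene", {
  sc <- test_scene(seed = 11)
  cal <- calibrate_scene(sc$cloud)
  expect_equal(cal$result$scale_factor * sc$truth$applied_scale, 1, tolerance = 0.005)
  # scale factor is exactly the diameter ratio
  expect_equal(cal$result$scale_factor,
               6 / cal$result$estimated_plate_diameter_raw, tolerance = 1e-12)
  # plate plane sits at its configured height, shoot above it
  plate <- cal$cloud[cal$cloud$component == "plate", ]
  expect_equal(median(plate$z), 1, tolerance = 0.05)
  shoot <- cal$cloud[cal$cloud$component == "shoot", ]
  expect_gt(mean(shoot$z), 1)
  expect_identical(cloud_frame(cal$cloud), "calibrated")
})

test_that("calibrated plate re-measures at its true radius across the scale regime", {
  for (s in c(0.0067, 0.02, 0.067)) {
    sp <- scene_spec(seed = 41, points_per_cm2 = 60, applied_scale = s)
    sc <- generate_scene(sp)
    cal <- calibrate_scene(sc$cloud)
    idx <- segment_plate(cal$cloud)
    P <- as.matrix(cal$cloud[idx, c("x", "y", "z")])
    pl <- fit_plate_plane(P)
    circ <- fit_circle(extract_boundary(P, pl))
    expect_equal(circ$radius, 3, tolerance = 0.03)
  }
})

test_that("a scene rotated 90 degrees calibrates to the same shoot height", {
  base <- scene_spec(seed = 42, points_per_cm2 = 60, applied_scale = 0.05,
                     applied_rotation = diag(3))
  rot <- base
  rot$applied_rotation <- rotation_about_axis(c(1, 0, 0), 90)
  h <- vapply(list(base, rot), function(sp) {
    sc <- generate_scene(sp)
    cal <- calibrate_scene(sc$cloud)
    shoot <- segment_shoot(sc$cloud, cal$result)
    plant_height(shoot)
  }, 0)
  expect_equal(h[1], h[2], tolerance = 0.005 * h[1])
})

test_that("an occluded plate triggers the residual warning path", {
  sp <- scene_spec(seed = 43, points_per_cm2 = 60, occlude_plate = TRUE)
  sc <- generate_scene(sp)
  expect_warning(cal <- calibrate_scene(sc$cloud), "occluded")
  expect_gt(length(cal$result$warnings), 0)
})

test_that("MAPE follows its definition and contracts", {
  expect_equal(evaluate_mape(c(1, 2, 3), c(1, 2, 3))$mape_pct, 0)
  expect_equal(evaluate_mape(6.06, 6)$mape_pct, 1, tolerance = 1e-9)
  m <- evaluate_mape(c(1.1, 2.4), c(1, 2))
  expect_equal(m$mape_pct, mean(c(10, 20)), tolerance = 1e-9)
  expect_equal(m$max_error_pct, 20, tolerance = 1e-9)
  # order invariance and non-negativity
  set.seed(44)
  est <- runif(10, 1, 2); tru <- runif(10, 1, 2)
  o <- sample(10)
  expect_equal(evaluate_mape(est, tru)$mape_pct, evaluate_mape(est[o], tru[o])$mape_pct)
  expect_gte(evaluate_mape(est, tru)$mape_pct, 0)
  expect_error(evaluate_mape(1, 0), "positive")
  expect_error(evaluate_mape(1:2, 1:3), "equal length")
})
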