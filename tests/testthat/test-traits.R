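test_that("plant height follows its definition and invariances", {
  pc <- point_cloud(cbind(runif(10), runif(10), c(0, 10, runif(8, 0, 10))))
  expect_equal(plant_height(pc), 10)
  up <- apply_transform(pc, similarity_transform(translation = c(0, 0, 5)))
  expect_equal(plant_height(up), 10)
  expect_error(plant_height(point_cloud(matrix(numeric(0), ncol = 3))), "empty")
})

test_that("pipeline height matches generator truth within a centimetre", {
  ts <- test_calibrated_shoot(seed = 11, height = 42)
  expect_equal(plant_height(ts$shoot), ts$scene$truth$height_cm, tolerance = 1)
})

test_that("leaf area recovers flat and curved analytic surfaces", {
  set.seed(71)
  # pipeline-regime sampling density (~50 points per cm^2)
  rect <- sample_rect(4000, 20, 2)
  expect_equal(as.numeric(leaf_area(rect)), 40, tolerance = 0.03)

  noisy <- sample_rect(2000, 20, 2) + matrix(rnorm(6000, 0, 0.05), ncol = 3)
  expect_equal(as.numeric(leaf_area(noisy)), 40, tolerance = 0.05)

  blade <- generate_leaf(20, 2, elev_deg = 60, tip_angle_deg = -30,
                         density_per_cm2 = 50)
  expect_equal(as.numeric(leaf_area(blade$points)), blade$area_cm2,
               tolerance = 0.05)
})

test_that("stem-like tubes contribute almost nothing to leaf area", {
  set.seed(72)
  th <- runif(3000, 0, 2 * pi); zz <- runif(3000, 0, 30)
  stem <- cbind(0.15 * cos(th), 0.15 * sin(th), zz)
  expect_lt(suppressWarnings(as.numeric(leaf_area(stem))), 1.5)
})

test_that("whole-shoot leaf area matches the analytic blade-area sum", {
  ts <- test_calibrated_shoot(seed = 11)
  est <- leaf_area(ts$shoot)
  expect_equal(as.numeric(est), ts$scene$truth$leaf_area_cm2,
               tolerance = 0.10 * ts$scene$truth$leaf_area_cm2)
})

test_that("planar-patch leaf-area error shrinks monotonically with density", {
  set.seed(73)
  errs <- vapply(c(12, 50, 200), function(d) {
    P <- sample_rect(round(40 * d), 20, 2)
    abs(as.numeric(leaf_area(P)) - 40) / 40
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("layered areas are compatible with generator truth", {
  ts <- test_calibrated_shoot(seed = 11)
  truth <- generate_scene(scene_spec(seed = 11, points_per_cm2 = 100,
                                     shoot = shoot_spec(shoot_height_cm = 40,
                                                        tiller_count = 4)),
                          truth_layers = TRUE)$truth
  la <- layered_projected_area(ts$shoot, n_layers = 4)
  expect_equal(la$area_cm2, truth$layer_projected_area_cm2,
               tolerance = 0.10 * max(truth$layer_projected_area_cm2))
})

test_that("trait extraction is complete, deterministic and scale-invariant", {
  ts <- test_calibrated_shoot(seed = 11)
  tr <- extract_traits(ts$shoot)
  expect_s3_class(tr, "shoot_traits")
  expect_length(tr$errors, 0)
  expect_gt(tr$plant_height_cm, 0)
  expect_gt(tr$leaf_area_cm2, 0)
  expect_gt(tr$convex_volume_cm3, 0)
  expect_true(tr$compactness > 0 && tr$compactness <= 1)
  expect_equal(nrow(tr$layer_projected_areas_cm2), 4)

  # deterministic: no hidden RNG
  tr2 <- extract_traits(ts$shoot)
  expect_equal(glance(tr), glance(tr2))

  # tidy/glance expose every trait family
  td <- tidy(tr)
  expect_setequal(td$trait[1:5], c("plant_height", "projected_area", "leaf_area",
                                   "convex_volume", "compactness"))
  expect_equal(nrow(glance(tr)), 1)
})

test_that("traits are invariant to rotation about Z and XY translation", {
  ts <- test_calibrated_shoot(seed = 11)
  shoot <- ts$shoot
  moved <- apply_transform(shoot, similarity_transform(
    rotation = rotation_about_axis(c(0, 0, 1), 137), translation = c(30, -12, 0)))
  a <- extract_traits(shoot); b <- extract_traits(moved)
  expect_equal(b$plant_height_cm, a$plant_height_cm, tolerance = 1e-9)
  expect_equal(b$projected_area_cm2, a$projected_area_cm2,
               tolerance = 0.01 * a$projected_area_cm2)
  expect_equal(b$leaf_area_cm2, a$leaf_area_cm2, tolerance = 0.01 * a$leaf_area_cm2)
  expect_equal(b$convex_volume_cm3, a$convex_volume_cm3,
               tolerance = 1e-6 * a$convex_volume_cm3)
  expect_equal(b$compactness, a$compactness, tolerance = 0.01 * a$compactness)
})

test_that("projected area never exceeds the convex hull of the projection", {
  set.seed(74)
  for (i in 1:5) {
    n <- 3000
    P <- cbind(rnorm(n), rnorm(n), runif(n))
    pa <- suppressWarnings(projected_area(P))
    xy <- unique(P[, 1:2]); h <- chull(xy)
    hull <- shootpheno:::polygon_area(xy[h, ])
    expect_lte(pa, hull * (1 + 1e-9))
  }
})

test_that("degenerate clouds produce per-trait errors, not crashes", {
  one <- point_cloud(matrix(c(0, 0, 0), 1, 3), frame = "calibrated")
  tr <- extract_traits(one)
  expect_gt(length(tr$errors), 0)
  expect_true(is.na(tr$leaf_area_cm2))
  expect_true(is.na(tr$convex_volume_cm3))
  g <- glance(tr)
  expect_equal(g$n_errors, length(tr$errors))
})
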