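test_that("cylinder cropping keeps the central region", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(cos(th), sin(th), 0)
  pc <- point_cloud(rbind(ring, c(0, 0, 0)))
  kept <- crop_cylinder(pc, 2 / 3)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, 0)

  # exact keep semantics: survivors are precisely the points within
  # fraction * MEC radius of the centroid
  set.seed(50)
  mix <- point_cloud(sample_disk(5000, 1, 0))
  kept <- crop_cylinder(mix, 2 / 3)
  r2 <- (mix$x - mean(mix$x))^2 + (mix$y - mean(mix$y))^2
  mec <- min_enclosing_circle(cbind(mix$x, mix$y))
  expect_equal(nrow(kept), sum(r2 <= (2 / 3 * mec$radius)^2))

  # uniform disk: survival is the area ratio (2/3)^2
  set.seed(51)
  disk <- point_cloud(sample_disk(40000, 1, 0))
  frac <- nrow(crop_cylinder(disk, 2 / 3)) / 40000
  expect_equal(frac, 4 / 9, tolerance = 0.02)

  expect_error(crop_cylinder(point_cloud(ring), 1e-6), "diameter_fraction")
})

test_that("ground removal cuts exactly the stated fraction of the extent", {
  pc <- point_cloud(cbind(0, 0, 0:99))
  out <- remove_ground(pc, 0.10)
  expect_equal(nrow(out), 90)
  expect_equal(min(out$z), 10)  # 0..9 fall below the 9.9 cut

  expect_equal(nrow(remove_ground(pc, 0)), 100)

  set.seed(52)
  u <- point_cloud(cbind(0, 0, runif(1e5)))
  removed <- 1 - nrow(remove_ground(u, 0.10)) / 1e5
  expect_equal(removed, 0.10, tolerance = 0.05)
  expect_error(remove_ground(point_cloud(cbind(1:5, 1, 2))), "extent")
})

test_that("random down-sampling is exact, seeded and stable", {
  set.seed(53)
  pc <- point_cloud(matrix(rnorm(30000), ncol = 3))
  out <- random_downsample(pc, 0.10, seed = 9)
  expect_equal(nrow(out), 1000)
  out2 <- random_downsample(pc, 0.10, seed = 9)
  expect_identical(out, out2)
  out3 <- random_downsample(pc, 0.10, seed = 10)
  expect_false(isTRUE(all.equal(out$x, out3$x)))
  expect_equal(nrow(random_downsample(pc, 1)), 10000)
  expect_error(random_downsample(pc, 0), "\\(0, 1\\]")
})

test_that("pot-rim cropping removes ground, plate and pot but keeps the shoot", {
  ts <- test_calibrated_shoot(seed = 11)
  cal_cloud <- ts$cal$cloud
  kept <- crop_below_pot_edge(cal_cloud, 12)
  expect_false(any(kept$component %in% c("ground", "plate")))
  expect_lt(sum(kept$component == "pot") / sum(cal_cloud$component == "pot"), 0.01)
  shoot_above <- cal_cloud$component == "shoot" & cal_cloud$z > 12.05
  expect_gt(sum(kept$component == "shoot") / sum(shoot_above), 0.99)

  # raw-frame input is rejected, empty result errors
  expect_error(crop_below_pot_edge(test_scene(11)$cloud, 12), "calibrated")
  expect_error(crop_below_pot_edge(cal_cloud, 1000), "pot rim")
  # pot_height 0 removes only the ground plane and below
  low <- crop_below_pot_edge(cal_cloud, 0)
  expect_true(all(low$z > 0))
})

test_that("statistical denoising removes isolated points but not dense structure", {
  set.seed(54)
  blob <- matrix(rnorm(3 * 500, 0, 0.1), ncol = 3)
  far <- c(30, 0, 0)
  pc <- point_cloud(rbind(blob, far))
  out <- statistical_denoise(pc, k = 10, std_ratio = 1)
  expect_equal(nrow(out), 500)
  expect_false(any(out$x > 20))

  grid <- as.matrix(expand.grid(x = 1:12, y = 1:12, z = 1:4))
  g <- statistical_denoise(point_cloud(grid), k = 8, std_ratio = 10)
  expect_equal(nrow(g), nrow(grid))

  expect_error(statistical_denoise(point_cloud(blob[1:5, ]), k = 50), "more than k")
})

test_that("denoising clears labelled speckle at minimal shoot loss", {
  audit <- denoise_audit(seed = 68)
  expect_gte(audit$removal, 0.95)
  expect_lte(audit$shoot_loss, 0.01)
})

test_that("the full segmentation chain isolates the shoot deterministically", {
  ts <- test_calibrated_shoot(seed = 11)
  shoot <- ts$shoot
  expect_gte(mean(shoot$component == "shoot"), 0.99)
  expect_identical(cloud_frame(shoot), "calibrated")
  counts <- attr(shoot, "stage_counts")
  expect_true(all(diff(counts[-1]) <= 0) || length(counts) > 1)

  again <- segment_shoot(ts$scene$cloud, ts$cal$result)
  expect_equal(as.data.frame(again), as.data.frame(shoot))

  # stages only ever filter: counts never grow
  expect_lte(counts["statistical_denoise"], counts["crop_below_pot_edge"])
  expect_lte(counts["remove_ground"], counts["crop_cylinder"])

  # point count lands in the platform's working regime for matched density
  expect_gt(nrow(shoot), 1e3)
  expect_lt(nrow(shoot), 1e5)
})

test_that("the same scene at two scales segments to the same calibrated cloud", {
  a <- scene_spec(seed = 55, points_per_cm2 = 60, applied_scale = 0.01,
                  applied_rotation = diag(3), noise_sigma_cm = 0, outlier_fraction = 0)
  b <- a; b$applied_scale <- 0.05
  sa <- generate_scene(a); sb <- generate_scene(b)
  ka <- segment_shoot(sa$cloud, calibrate_scene(sa$cloud)$result)
  kb <- segment_shoot(sb$cloud, calibrate_scene(sb$cloud)$result)
  expect_equal(nrow(ka), nrow(kb), tolerance = 0.02)
  expect_equal(plant_height(ka), plant_height(kb), tolerance = 0.005 * plant_height(ka))

  expect_error(calibrate_scene(point_cloud(matrix(rnorm(30), ncol = 3))), "colors")
})
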