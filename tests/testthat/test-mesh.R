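test_that("triangulation covers simple planar layouts exactly", {
  tri <- triangulate_surface(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(nrow(tri$triangles), 1)
  expect_equal(tri$area, 0.5, tolerance = 1e-12)

  g <- as.matrix(expand.grid(x = seq(0, 1, 0.05), y = seq(0, 1, 0.05)))
  expect_equal(triangulate_surface(g)$area, 1, tolerance = 1e-6)
})

test_that("the edge cap prevents bridging distant patches", {
  set.seed(61)
  g <- as.matrix(expand.grid(x = seq(0, 1, 0.04), y = seq(0, 1, 0.04)))
  g <- g + matrix(runif(length(g), -0.005, 0.005), ncol = 2)
  mesh <- triangulate_surface(rbind(g, cbind(g[, 1] + 5, g[, 2])))
  # no triangle may span the 4-unit gap between the two patches
  P <- mesh$vertices
  spans <- apply(matrix(P[mesh$triangles, 1], ncol = 3), 1,
                 function(x) diff(range(x)))
  expect_lt(max(spans), 4)
  expect_equal(mesh$area, 2, tolerance = 0.03)
})

test_that("collinear input degrades to an empty mesh with a warning", {
  expect_warning(m <- triangulate_surface(cbind(1:10, 1:10)), "collinear|empty")
  expect_equal(nrow(m$triangles), 0)
  expect_equal(m$area, 0)
})

test_that("projected area matches analytic footprints", {
  set.seed(62)
  sq <- sample_rect(120000, 10, 10)
  expect_equal(projected_area(sq, voxel_size_cm = 0.05), 100, tolerance = 0.02)

  disk <- sample_disk(60000, 5, 0)
  expect_equal(projected_area(disk, voxel_size_cm = 0.1), pi * 25, tolerance = 0.02)

  # L of two unit squares touching at one corner: concavity preserved,
  # area 2 but convex hull area 3
  L <- rbind(sample_rect(30000, 1, 1),
             sweep(sample_rect(30000, 1, 1), 2, c(1, 1, 0), "+"))
  a <- projected_area(L, voxel_size_cm = 0.015)
  expect_equal(a, 2, tolerance = 0.03)
  expect_lt(a, 0.9 * 3)

  expect_warning(z <- projected_area(cbind(1:50, 1:50, 0)), "degenerate|collinear")
  expect_equal(z, 0)
})

test_that("layered projected area slices consistently", {
  ts <- test_calibrated_shoot(seed = 11)
  one <- layered_projected_area(ts$shoot, n_layers = 1)
  expect_equal(one$area_cm2, projected_area(ts$shoot), tolerance = 1e-9)

  # vertical cylinder shell of finite wall thickness: four identical annuli
  set.seed(63)
  th <- runif(60000, 0, 2 * pi); zz <- runif(60000, 0, 20)
  rr <- runif(60000, 4.6, 5)
  shell <- point_cloud(cbind(rr * cos(th), rr * sin(th), zz), frame = "calibrated")
  la <- layered_projected_area(shell, n_layers = 4, voxel_size_cm = 0.1)
  expect_equal(nrow(la), 4)
  expect_lt(diff(range(la$area_cm2)) / mean(la$area_cm2), 0.05)

  # every point belongs to exactly one layer
  expect_equal(sum(la$n_points), nrow(shell))
})

test_that("convex hull volume is exact on polytopes and converges on smooth bodies", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_volume(cube), 1, tolerance = 1e-12)

  set.seed(64)
  # dense ball: rejection-sampled interior points
  n <- 60000
  B <- matrix(runif(3 * n, -1, 1), ncol = 3)
  B <- B[rowSums(B^2) <= 1, ]
  expect_equal(convex_volume(2 * B), (4 / 3) * pi * 8, tolerance = 0.02 * (4 / 3) * pi * 8)

  # interior points never change the hull
  withins <- rbind(cube, matrix(0.25 + 0.5 * runif(300), ncol = 3))
  expect_equal(convex_volume(withins), 1, tolerance = 1e-12)

  # monotone under point addition
  v1 <- convex_volume(B[1:2000, ])
  v2 <- convex_volume(rbind(B[1:2000, ], c(2, 0, 0)))
  expect_gt(v2, v1)

  expect_warning(flat <- convex_volume(cbind(runif(50), runif(50), 1)), "coplanar")
  expect_equal(flat, 0)
  expect_error(convex_volume(cube[1:3, ]), "at least 4")
})

test_that("compactness is the footprint-to-hull ratio", {
  set.seed(65)
  disk <- sample_disk(60000, 5, 0)
  expect_equal(compactness(disk, voxel_size_cm = 0.1), 1, tolerance = 0.03)

  # plus sign of five unit squares: 5 / hull area, well below 1
  sqs <- list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  plus <- do.call(rbind, lapply(sqs, function(o) {
    sweep(sample_rect(20000, 1, 1), 2, c(o[1], o[2], 0), "+")
  }))
  cp <- compactness(plus, voxel_size_cm = 0.02)
  hull_area <- 5 + 4 * 0.5
  expect_equal(cp, 5 / hull_area, tolerance = 0.05)
  expect_lt(cp, 1)

  # a spread star is less compact than a filled rosette of equal hull
  th <- rep(seq(0, 2 * pi, length.out = 7)[-7], each = 3000)
  rr <- runif(length(th), 0, 5)
  star <- cbind(rr * cos(th) + rnorm(length(th), 0, 0.05),
                rr * sin(th) + rnorm(length(th), 0, 0.05), 0)
  rosette <- sample_disk(18000, 5, 0)
  expect_lt(compactness(star, voxel_size_cm = 0.1),
            compactness(rosette, voxel_size_cm = 0.1))

  expect_error(compactness(cbind(1:9, 1:9, 0)), "degenerate")
})

test_that("minimum enclosing circle is exact on known configurations", {
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  m <- min_enclosing_circle(sq)
  expect_equal(m$radius, sqrt(2), tolerance = 1e-9)
  expect_equal(m$center, c(0, 0), tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(66)
  inside <- cbind(runif(500, -0.9, 0.9), runif(500, -0.9, 0.9))
  m2 <- min_enclosing_circle(rbind(sq, inside))
  expect_equal(m2$radius, sqrt(2), tolerance = 1e-9)

  two <- rbind(c(0, 0), c(4, 0))
  expect_equal(min_enclosing_circle(two)$radius, 2, tolerance = 1e-12)
})
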