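test_that("PLY round trip preserves points and colors", {
  set.seed(1)
  n <- 10000
  P <- matrix(runif(3 * n, -5, 5), ncol = 3)
  C <- matrix(round(runif(3 * n) * 255) / 255, ncol = 3)
  pc <- point_cloud(P, colors = C)
  f <- withr::local_tempfile(fileext = ".ply")
  save_point_cloud(pc, f)
  back <- load_point_cloud(f)
  expect_equal(nrow(back), n)
  # coordinates within declared write precision (6 significant digits)
  expect_lt(max(abs(cloud_positions(back) - P)), 1e-4)
  # 8-bit color channels survive bit-identically
  expect_identical(cloud_colors(back), C)
})

test_that("hand-written ASCII PLY fixtures parse", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header",
               "0 0 0 255 0 0", "1 0 0 255 0 0", "0 1 0 255 0 0"), f)
  pc <- load_point_cloud(f)
  expect_equal(nrow(pc), 3)
  expect_true(all(pc$r == 1 & pc$g == 0 & pc$b == 0))

  # colorless and empty clouds round-trip too
  f2 <- withr::local_tempfile(fileext = ".ply")
  save_point_cloud(point_cloud(matrix(1:6, ncol = 3)), f2)
  expect_false(has_colors(load_point_cloud(f2)))
  f3 <- withr::local_tempfile(fileext = ".ply")
  save_point_cloud(point_cloud(matrix(numeric(0), ncol = 3)), f3)
  expect_equal(nrow(load_point_cloud(f3)), 0)
})

test_that("binary little-endian PLY is read", {
  f <- withr::local_tempfile(fileext = ".ply")
  con <- file(f, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0", "element vertex 2",
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green", "property uchar blue",
               "end_header"), con)
  for (row in list(c(1.5, 2.5, 3.5), c(-1, 0, 2))) {
    writeBin(row, con, size = 4, endian = "little")
    writeBin(as.raw(c(255, 128, 0)), con)
  }
  close(con)
  pc <- load_point_cloud(f)
  expect_equal(pc$x, c(1.5, -1))
  expect_equal(pc$z, c(3.5, 2))
  expect_equal(pc$g, c(128, 128) / 255)
})

test_that("XYZRGB text parses with 8-bit rescale and errors name the line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 255 0 0", "1 2 3 0 255 0"), f)
  pc <- load_point_cloud(f, format = "xyzrgb")
  expect_equal(pc$r, c(1, 0))
  expect_equal(pc$g, c(0, 1))
  expect_equal(pc$y[2], 2)

  writeLines(c("0 0 0 255 0 0", "1 2 oops 0 255 0"), f)
  expect_error(load_point_cloud(f, format = "xyzrgb"), "line 2")
  expect_error(load_point_cloud("does/not/exist.ply"), "not found")
})

test_that("non-finite coordinates are dropped at construction with a count", {
  expect_message(pc <- point_cloud(rbind(c(0, 0, 0), c(NA, 1, 1), c(Inf, 0, 0), c(1, 1, 1))),
                 "2 point")
  expect_equal(nrow(pc), 2)
})

test_that("similarity transforms behave algebraically", {
  seg <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(cloud_positions(apply_transform(seg, similarity_transform())),
               cloud_positions(seg))
  doubled <- apply_transform(seg, similarity_transform(scale = 2))
  expect_equal(cloud_positions(doubled)[2, ], c(x = 2, y = 0, z = 0))

  set.seed(7)
  for (i in 1:5) {
    tf <- similarity_transform(exp(rnorm(1)), random_rotation(), rnorm(3))
    P <- matrix(rnorm(60), ncol = 3)
    pc <- point_cloud(P)
    back <- apply_transform(apply_transform(pc, tf), invert_transform(tf))
    expect_lt(max(abs(cloud_positions(back) - P)), 1e-9)
    # composition associates: T2 o T1 applied at once equals sequential
    tf2 <- similarity_transform(exp(rnorm(1)), random_rotation(), rnorm(3))
    seqq <- apply_transform(apply_transform(pc, tf), tf2)
    once <- apply_transform(pc, compose_transforms(tf2, tf))
    expect_lt(max(abs(cloud_positions(seqq) - cloud_positions(once))), 1e-9)
  }
})

test_that("transforms preserve pairwise distance ratios and rigid distances", {
  set.seed(8)
  P <- matrix(rnorm(30), ncol = 3)
  d0 <- dist(P)
  rigid <- similarity_transform(1, random_rotation(), c(1, -2, 3))
  expect_equal(as.numeric(dist(cloud_positions(apply_transform(point_cloud(P), rigid)))),
               as.numeric(d0), tolerance = 1e-12)
  scaled <- similarity_transform(3.7, random_rotation(), rnorm(3))
  d1 <- dist(cloud_positions(apply_transform(point_cloud(P), scaled)))
  expect_equal(as.numeric(d1) / as.numeric(d0), rep(3.7, length(d0)), tolerance = 1e-12)
})

test_that("invalid rotations are rejected", {
  bad <- diag(3); bad[1, 1] <- 2
  expect_error(similarity_transform(rotation = bad), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(similarity_transform(rotation = refl), "orthonormal")
})
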