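test_that("point mapping is exactly invertible for random similarity transforms", {
  set.seed(101)
  worst <- 0
  for (i in 1:200) {
    t <- similarity_transform(scale = runif(2, 0.3, 3),
                              rotation_deg = runif(1, -360, 360),
                              translation = runif(2, -100, 100),
                              pivot = runif(2, -50, 50))
    p <- matrix(runif(20, -200, 200), 10, 2)
    expect_lt(max(abs(map_points(map_points(p, t, "forward"), t, "inverse") - p)), 1e-9)
    worst <- max(worst, max(abs(map_points(p, compose_transforms(invert_transform(t), t)) - p)))
  }
  expect_lt(worst, 1e-9)
})

test_that("transform composition equals the composed matrix product", {
  t1 <- similarity_transform(scale = c(2, 0.5), rotation_deg = 30, translation = c(5, -3))
  t2 <- similarity_transform(scale = c(1.2, 1.2), rotation_deg = -75, translation = c(-8, 2),
                             pivot = c(4, 4))
  tc <- compose_transforms(t2, t1)
  p <- matrix(runif(10, -50, 50), 5, 2)
  expect_equal(map_points(p, tc), map_points(map_points(p, t1), t2), tolerance = 1e-12)
})

test_that("resize to the coarse grid follows the stated scaling convention", {
  cine <- cine_series(array(runif(160 * 160 * 2), c(160, 160, 2)), c(1, 1), 1)
  rs <- resize_to_network_grid(cine)
  expect_identical(rs$cine$frames, cine$frames)       # identity case
  expect_equal(rs$transform$matrix, cbind(diag(2), c(0, 0)))

  cine2 <- cine_series(array(runif(320 * 320), c(320, 320, 1)), c(1, 1), 1)
  rs2 <- resize_to_network_grid(cine2)
  expect_equal(rs2$transform$scale, c(0.5, 0.5))
  expect_equal(as.numeric(map_points(c(100, 60), rs2$transform)), c(50, 30))

  cine3 <- cine_series(array(runif(240 * 160), c(240, 160, 1)), c(1, 1), 1)
  rs3 <- resize_to_network_grid(cine3)
  expect_equal(rs3$transform$scale, c(1, 160 / 240))
  p <- matrix(runif(20, 0, 150), 10, 2)
  expect_lt(max(abs(map_points(map_points(p, rs3$transform), rs3$transform, "inverse") - p)), 1e-9)

  expect_error(resize_to_network_grid(cine_series(matrix(0, 1, 5), c(1, 1))), "degenerate")
})

test_that("standardization of an already-standard annotation is the identity", {
  g <- standard_grid()
  pts <- array(0, c(3, 2, 2))
  pts[, 1, 1] <- 60.5; pts[, 2, 1] <- 100.5
  pts[, 1, 2] <- c(58.5, 62, 64); pts[, 2, 2] <- c(58.5, 62, 64)  # moves down
  ann <- mv_annotation(pts, view = "2ch")
  cine <- cine_series(array(0, c(g$size, 3)), pixel_spacing = g$spacing_mm)
  t <- estimate_standardization(ann, cine)
  d <- decompose_transform(t)
  expect_equal(d$scale, c(1, 1), tolerance = 1e-12)
  expect_equal(d$rotation_deg %% 360, 0, tolerance = 1e-9)
  expect_equal(as.numeric(map_points(c(80.5, 58.5), t)), c(80.5, 58.5), tolerance = 1e-9)
})

test_that("standardization rescales anisotropic spacing and centres the valve", {
  pts <- array(0, c(3, 2, 2))
  pts[, 1, ] <- matrix(c(10, 10, 10, 10, 12, 13), 3, 2)  # x then y per frame
  pts[, 2, ] <- matrix(c(20, 20, 20, 10, 12, 13), 3, 2)
  ann <- mv_annotation(pts, view = "2ch")
  cine <- cine_series(array(0, c(40, 40, 3)), pixel_spacing = c(1.5, 1.5))
  t <- estimate_standardization(ann, cine)
  d <- decompose_transform(t)
  expect_equal(d$scale, c(2, 2), tolerance = 1e-12)
  expect_equal(d$rotation_deg %% 360, 0, tolerance = 1e-9)
  expect_equal(as.numeric(map_points(c(15, 10), t)), c(80.5, 58.5), tolerance = 1e-9)
})

test_that("a vertical valve segment is rotated so the motion points down", {
  # p1 -> p2 along +y, motion towards larger column values
  pts <- array(0, c(4, 2, 2))
  pts[, 1, 1] <- c(50, 51, 52, 52); pts[, 1, 2] <- 40
  pts[, 2, 1] <- c(50, 51, 52, 52); pts[, 2, 2] <- 60
  ann <- mv_annotation(pts)
  cine <- cine_series(array(0, c(100, 100, 4)), pixel_spacing = c(0.75, 0.75))
  t <- estimate_standardization(ann, cine)
  d <- decompose_transform(t)
  expect_equal(abs(((d$rotation_deg + 180) %% 360) - 180), 90, tolerance = 1e-9)
  mids <- annotation_midpoints(map_annotation(ann, t))
  expect_true(all(mids[-1, 2] > mids[1, 2]))  # motion maps to larger rows
  f0 <- annotation_frame(map_annotation(ann, t), 0)
  expect_equal(f0[1, 2], f0[2, 2], tolerance = 1e-9)  # horizontal
})

test_that("degenerate standardization inputs raise the documented errors", {
  pts <- array(1, c(3, 2, 2))
  cine <- cine_series(array(0, c(20, 20, 3)), c(1, 1))
  expect_error(estimate_standardization(mv_annotation(pts), cine), "degenerate")
  one <- array(c(1, 5, 1, 1), c(1, 2, 2))
  expect_error(estimate_standardization(mv_annotation(one), cine), "ambiguous")
})

test_that("standardization from rendered ground truth places the valve canonically", {
  for (rot in c(0, 57, 133, 241, 318)) {
    out <- quick_cine(seed = rot + 1, rotation = rot)
    t <- estimate_standardization(out$annotation, out$cine)
    m <- map_annotation(out$annotation, t)
    f0 <- annotation_frame(m, 0)
    ctr <- standard_grid()$center
    expect_lt(sqrt(sum((colMeans(f0) - ctr)^2)), 0.5)            # midpoint at centre
    ang <- atan2(f0[2, 2] - f0[1, 2], f0[2, 1] - f0[1, 1]) * 180 / pi
    expect_lt(abs(ang), 0.5)                                     # horizontal, p1 left
    mids <- annotation_midpoints(m)
    expect_gt(mean(mids[-1, 2]), f0[1, 2])                       # apex below
  }
})

test_that("apply_transform is a single-pass resampling consistent with map_points", {
  g <- standard_grid()
  out <- quick_cine(seed = 5, rotation = 70)
  t <- estimate_standardization(out$annotation, out$cine)

  # identity on an already-standard cine
  std <- apply_transform(out$cine, t)
  ident <- similarity_transform(output_size = g$size)
  expect_equal(apply_transform(std$cine, ident, spacing_mm = g$spacing_mm)$cine$frames,
               std$cine$frames, tolerance = 1e-12)

  # a one-hot marker at a ground-truth point lands at its mapped location
  f0 <- annotation_frame(out$annotation, 0)
  marker <- matrix(0, dim(out$cine$frames)[1], dim(out$cine$frames)[2])
  marker[round(f0[1, 2]) + 1L, round(f0[1, 1]) + 1L] <- 1
  mcine <- cine_series(marker, out$cine$pixel_spacing)
  mapped <- apply_transform(mcine, t)$cine$frames[, , 1]
  hot <- which(mapped == max(mapped), arr.ind = TRUE)[1, ]
  want <- map_points(round(f0[1, , drop = FALSE]), t)
  expect_lt(sqrt((hot[2] - 1 - want[1])^2 + (hot[1] - 1 - want[2])^2), 1)

  # pure 90-degree rotation of a one-hot image
  img <- matrix(0, 21, 21); img[6, 16] <- 1  # x=15, y=5
  rot90 <- similarity_transform(rotation_deg = 90, pivot = c(10, 10),
                                translation = c(10, 10), output_size = c(21, 21))
  rimg <- apply_transform(cine_series(img, c(1, 1)), rot90,
                          spacing_mm = 1)$cine$frames[, , 1]
  want <- map_points(c(15, 5), rot90)  # -> (15, 15)
  hot <- which(rimg == max(rimg), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric(c(hot[2], hot[1]) - 1), as.numeric(want), tolerance = 0.5)

  # crop fully outside the field: all zeros, no error
  far <- similarity_transform(translation = c(10000, 10000), output_size = c(10, 10))
  expect_true(all(apply_transform(cine_series(img, c(1, 1)), far,
                                  spacing_mm = 1)$cine$frames == 0))
})

test_that("transforms serialize to JSON and replay exactly", {
  t <- similarity_transform(scale = c(1.7, 0.6), rotation_deg = -33,
                            translation = c(4.25, -9.5), pivot = c(7, 3),
                            output_size = c(64, 80))
  t2 <- transform_from_json(transform_to_json(t))
  expect_equal(t2$matrix, t$matrix, tolerance = 0)
  expect_identical(t2$output_size, t$output_size)
  p <- matrix(runif(10), 5, 2)
  expect_identical(map_points(p, t2), map_points(p, t))
})
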