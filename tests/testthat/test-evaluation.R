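make_ann <- function(m) {
  # m: n x 4 matrix (x1, y1, x2, y2)
  mv_annotation(m)
}

test_that("Euclidean error respects the anisotropic spacing pairing", {
  gt <- make_ann(rbind(c(10, 10, 30, 10), c(10, 12, 30, 12)))
  expect_true(all(euclidean_error(gt, gt, 1) == 0))

  pred <- make_ann(rbind(c(13, 14, 33, 14), c(13, 16, 33, 16)))  # offset (3, 4)
  expect_true(all(abs(euclidean_error(pred, gt, 1.0) - 5) < 1e-12))
  e <- euclidean_error(pred, gt, c(2.0, 1.0))
  expect_true(all(abs(e - sqrt(52)) < 1e-12))

  short <- make_ann(rbind(c(10, 10, 30, 10)))
  expect_error(euclidean_error(short, gt, 1), "different frames")
})

test_that("Euclidean error is invariant under a common rigid transform", {
  set.seed(77)
  gt <- make_ann(matrix(runif(20, 10, 90), 5, 4))
  pred <- make_ann(annotation_matrix(gt) + matrix(rnorm(20), 5, 4))
  e0 <- euclidean_error(pred, gt, 1)
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rig <- function(a) {
    p <- a$points
    for (i in seq_len(dim(p)[1])) for (j in 1:2)
      p[i, j, ] <- as.numeric(R %*% p[i, j, ]) + c(7, -4)
    mv_annotation(p)
  }
  expect_equal(euclidean_error(rig(pred), rig(gt), 1), e0, tolerance = 1e-9)
})

test_that("angular error is the acute inner angle, symmetric, point-order invariant", {
  gt <- make_ann(rbind(c(10, 20, 40, 20)))
  expect_equal(angular_error(gt, gt), 0)

  perp <- make_ann(rbind(c(25, 5, 25, 35)))
  expect_equal(angular_error(perp, gt), 90)

  th <- 10 * pi / 180; ctr <- c(25, 20)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- t(apply(rbind(c(10, 20), c(40, 20)), 1, function(p) R %*% (p - ctr) + ctr))
  pred <- make_ann(matrix(c(rot[1, ], rot[2, ]), 1, 4))
  expect_equal(angular_error(pred, gt), 10, tolerance = 1e-9)
  expect_equal(angular_error(gt, pred), angular_error(pred, gt))
  swapped <- make_ann(rbind(c(rot[2, ], rot[1, ])))
  expect_equal(angular_error(swapped, gt), 10, tolerance = 1e-9)

  degen <- make_ann(rbind(c(5, 5, 5, 5)))
  expect_true(is.na(angular_error(degen, gt)))
})

test_that("in-plane point offsets decouple displacement error from Euclidean error", {
  out <- quick_cine(seed = 13, n_frames = 10L, rotation = 30)
  gt <- out$annotation
  sp <- out$cine$pixel_spacing
  # shift every point 3 px along its frame's own plane direction
  pts <- gt$points
  for (i in seq_len(dim(pts)[1])) {
    dirv <- pts[i, 2, ] - pts[i, 1, ]; dirv <- dirv / sqrt(sum(dirv^2))
    for (j in 1:2) pts[i, j, ] <- pts[i, j, ] + 3 * dirv
  }
  pred <- mv_annotation(pts, view = gt$view)
  expect_gt(mean(euclidean_error(pred, gt, sp)), 3)
  dp <- plane_displacement(pred, sp, rr_s = 1)
  dg <- plane_displacement(gt, sp, rr_s = 1)
  expect_lt(max(abs(displacement_error(dp, dg))), 1e-9)

  # signed-difference summaries
  expect_equal(displacement_error(dg, dg), rep(0, 10))
  shifted <- displacement_curve(dg$times, dg$values + 0.5)
  expect_equal(mean(displacement_error(shifted, dg)), 0.5)
  expect_equal(sd(displacement_error(shifted, dg)), 0)
  expect_error(displacement_error(displacement_curve(0:3 / 3, 1:4), dg), "length")
})

test_that("ICC(2,1) equals the brute-force ANOVA oracle on random tables", {
  expect_equal(icc_agreement(1:10, 1:10)$icc, 1.0)
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    m <- matrix(rnorm(n * 2, sd = runif(1, 0.5, 5)), n, 2) + runif(1, -10, 10)
    expect_lt(abs(icc_agreement(m[, 1], m[, 2])$icc - oracle_icc21(m)), 1e-10)
  }
  # large independent noise drives agreement towards zero
  x <- rnorm(400, 10, 1); y <- x + rnorm(400, 0, 10)
  expect_lt(abs(icc_agreement(x, y)$icc), 0.2)

  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_error(icc_agreement(1:2, 2:3), "3 complete pairs")
})

test_that("the ICC confidence interval matches an independent reference", {
  # reference values computed with an independent two-way random-effects
  # absolute-agreement implementation (single measures)
  x <- c(5.558, 14.732, 7.13, 7.24, 4.007, 9.183, 9.054, 8.115, 9.681,
         11.284, 7.667, 6.118)
  y <- c(5.278, 15.244, 7.478, 7.037, 5.696, 10.024, 10.061, 8.322, 10.405,
         13.791, 9.179, 6.316)
  r <- icc_agreement(x, y)
  expect_equal(r$icc, 0.933836, tolerance = 1e-6)
  expect_equal(r$ci, c(0.580364, 0.983890), tolerance = 1e-6)
  expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])
})

test_that("Bland-Altman bias and limits follow the sd of the differences", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x)$loa, c(0, 0))
  r <- bland_altman(x, x + 0.5)
  expect_equal(r$bias, 0.5); expect_equal(r$loa, c(0.5, 0.5))
  r2 <- bland_altman(c(0, 0, 0), c(-1, 0, 1))
  expect_equal(r2$bias, 0)
  expect_equal(r2$loa, c(-1.96, 1.96))
})

test_that("agreement_stats combines ICC, Bland-Altman and regression", {
  set.seed(8)
  x <- rnorm(30, 12, 3); y <- 1.05 * x - 0.4 + rnorm(30, 0, 0.2)
  a <- agreement_stats(x, y)
  expect_equal(a$regression$slope, 1.05, tolerance = 0.05)
  expect_equal(a$regression$intercept, -0.4, tolerance = 0.6)
  expect_gt(a$regression$r, 0.99)
  expect_equal(a$n, 30L)
  expect_equal(a$ba$loa[2] - a$ba$bias, 1.96 * a$ba$sd_diff)
})

test_that("the stage-wise report pools metrics per stage with oracle-zero errors", {
  results <- list(); gts <- list()
  for (seed in 1:3) {
    out <- quick_cine(seed = seed, n_frames = 8L, rotation = 40 * seed)
    oracle <- oracle_regressor(out$annotation)
    results[[seed]] <- track_mv(out$cine, oracle, oracle)
    gts[[seed]] <- out$annotation
  }
  rep <- stagewise_report(results, gts, spacings = c(1.5, 1.5), rr_s = 1)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$stage, c("stage1", "stage1+2", "stage1+2+2"))
  expect_true(all(rep$euclid_mean_mm < 1e-6))
  expect_true(all(abs(rep$disp_err_mean_mm) < 1e-6))
  expect_true(all(rep$frames_excluded == 0))
  tmp <- tempfile(); write_report(rep, paste0(tmp, ".csv"), paste0(tmp, ".json"))
  expect_true(file.exists(paste0(tmp, ".csv")))
  expect_true(file.exists(paste0(tmp, ".json")))
  expect_error(stagewise_report(list(), list(), 1), "no tracking results")
})
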