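test_that("displacement profile honours amplitude, endpoints and phase structure", {
  flat <- generate_displacement_profile(quick_motion(mapse_mm = 0, n_frames = 20))
  expect_true(all(flat$values == 0))

  p <- motion_profile_params(mapse_mm = 15, n_frames = 30)
  d <- generate_displacement_profile(p)
  expect_equal(max(d$values), 15.0)
  expect_equal(d$values[1], 0)
  expect_equal(d$values[30], 0)
  imax <- which.max(d$values) - 1L
  expect_equal(imax / 29, p$systole_fraction, tolerance = 0.5 / 29)

  # exactly three sign-consistent derivative lobes: descent(+), recoil(-),
  # kick(-), verified by exhaustive scan of the sampled curve
  set.seed(9)
  for (i in 1:20) {
    pp <- motion_profile_params(mapse_mm = runif(1, 8, 18),
                                hr_bpm = runif(1, 50, 90),
                                n_frames = sample(25:50, 1),
                                systole_fraction = runif(1, 0.32, 0.40),
                                diastasis_fraction = runif(1, 0.24, 0.32),
                                atrial_kick_fraction_of_mapse = runif(1, 0.18, 0.30))
    dd <- generate_displacement_profile(pp)
    dv <- diff(dd$values)
    runs <- rle(sign(round(dv, 12)))
    expect_identical(runs$values[runs$values != 0], c(1, -1, -1))
    v <- dd$values
    strict_peaks <- which(v > c(-Inf, head(v, -1)) & v > c(tail(v, -1), Inf))
    expect_length(strict_peaks, 1L)                # single global maximum
    expect_equal(v[strict_peaks], pp$mapse_mm)
  }
})

test_that("invalid motion fractions raise parameter errors", {
  expect_error(motion_profile_params(systole_fraction = 0), "fractions")
  expect_error(motion_profile_params(diastasis_fraction = 1), "fractions")
  expect_error(motion_profile_params(mapse_mm = -1), "mapse")
  expect_error(motion_profile_params(n_frames = 1), "n_frames")
})

test_that("rendering is bit-deterministic under a fixed seed", {
  a <- quick_cine(seed = 42, noise_sd = 0.05)
  b <- quick_cine(seed = 42, noise_sd = 0.05)
  expect_identical(a$cine$frames, b$cine$frames)
  expect_identical(a$annotation$points, b$annotation$points)
  c <- quick_cine(seed = 43, noise_sd = 0.05)
  expect_false(identical(a$cine$frames, c$cine$frames))
})

test_that("frame-0 annulus geometry is analytic, not pixel-derived", {
  out <- render_cine(quick_motion(), quick_render(heart_rotation_deg = 0),
                     seed = 1)
  f0 <- annotation_frame(out$annotation, 0)
  sep_mm <- sqrt(sum(((f0[2, ] - f0[1, ]) * out$cine$pixel_spacing)^2))
  expect_lt(abs(sep_mm - 28), 1e-9)
  expect_lt(f0[1, 1], f0[2, 1])   # first point on the left at rotation 0
})

test_that("derived displacement is invariant to rendering resolution", {
  m <- quick_motion(n_frames = 16)
  outA <- render_cine(m, quick_render(pixel_spacing_mm = 1.3, image_size = c(128, 128)), seed = 3)
  outB <- render_cine(m, quick_render(pixel_spacing_mm = 1.7, image_size = c(128, 128)), seed = 3)
  dA <- plane_displacement(outA$annotation, outA$cine$pixel_spacing, rr_s = 1)
  dB <- plane_displacement(outB$annotation, outB$cine$pixel_spacing, rr_s = 1)
  expect_lt(max(abs(dA$values - dB$values)), 1e-6)
  # and it reproduces the generating profile exactly
  prof <- generate_displacement_profile(m)
  expect_lt(max(abs(dA$values - prof$values)), 1e-6)
})

test_that("the annotation convention shifts points but not the displacement curve", {
  m <- quick_motion(n_frames = 16)
  rA <- quick_render(heart_rotation_deg = 40)
  rB <- quick_render(heart_rotation_deg = 40,
                     annotation_convention = "basal_myocardium",
                     convention_offset_mm = 2)
  a <- render_cine(m, rA, seed = 4); b <- render_cine(m, rB, seed = 4)
  expect_identical(a$cine$frames, b$cine$frames)   # images identical
  shift <- sqrt(rowSums(((annotation_frame(b$annotation, 0) -
                          annotation_frame(a$annotation, 0)) *
                         matrix(a$cine$pixel_spacing, 2, 2, byrow = TRUE))^2))
  expect_equal(as.numeric(shift), c(2, 2), tolerance = 1e-9)
  dA <- plane_displacement(a$annotation, a$cine$pixel_spacing, rr_s = 1)
  dB <- plane_displacement(b$annotation, b$cine$pixel_spacing, rr_s = 1)
  expect_lt(abs(max(dA$values) - max(dB$values)), 1e-6)
})

test_that("a valve point leaving the field names the offending frame", {
  r <- render_params(image_size = c(48, 48), pixel_spacing_mm = 1.5,
                     heart_center_px = c(24, 44), annulus_width_mm = 30)
  expect_error(render_cine(quick_motion(mapse_mm = 18), r, seed = 1),
               "frame [0-9]+")
})

test_that("dataset manifests count, split and reproduce correctly", {
  ds <- make_dataset(10, seed = 77, split = c(train = 0.8, test = 0.2),
                     write_images = FALSE)
  expect_length(ds$subjects, 10L)
  splits <- sapply(ds$subjects, `[[`, "split")
  expect_equal(sum(splits == "train"), 8L)
  expect_equal(sum(splits == "test"), 2L)
  expect_equal(sum(sapply(ds$subjects, function(s) length(s$views))), 20L)

  ds2 <- make_dataset(10, seed = 77, split = c(train = 0.8, test = 0.2),
                      write_images = FALSE)
  expect_identical(lapply(ds$subjects, `[[`, "params"),
                   lapply(ds2$subjects, `[[`, "params"))
  expect_identical(ds$subjects[[3]]$views[["2ch"]]$data$cine$frames,
                   ds2$subjects[[3]]$views[["2ch"]]$data$cine$frames)

  expect_error(make_dataset(10, split = c(train = 0.9, test = 0.2)), "split")
  expect_error(make_dataset(1), "n_subjects")
})

test_that("collapsed parameter ranges freeze everything but the noise seed", {
  pt <- lapply(default_param_ranges(), function(r) rep(mean(r), 2))
  pt$n_frames <- c(20, 20); pt$image_size <- c(100, 100)
  pt$heart_rotation_deg <- c(30, 30)
  ds <- make_dataset(4, seed = 5, param_ranges = pt, write_images = FALSE)
  motions <- lapply(ds$subjects, function(s) s$params$motion)
  expect_identical(motions[[1]], motions[[2]])
  expect_identical(ds$subjects[[1]]$params$render, ds$subjects[[3]]$params$render)
  # same parameters, different noise realizations
  expect_false(identical(ds$subjects[[1]]$views[["2ch"]]$data$cine$frames,
                         ds$subjects[[2]]$views[["2ch"]]$data$cine$frames))
  expect_identical(ds$subjects[[1]]$views[["2ch"]]$data$annotation$points,
                   ds$subjects[[2]]$views[["2ch"]]$data$annotation$points)
})
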