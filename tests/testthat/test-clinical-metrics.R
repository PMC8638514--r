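test_that("plane displacement reduces to point-line geometry", {
  pts <- array(0, c(3, 2, 2))
  pts[1, , ] <- rbind(c(10, 20), c(30, 20))
  pts[2, , ] <- rbind(c(10, 25), c(30, 25))          # rigid 5 px down
  pts[3, , ] <- rbind(c(10, 24), c(30, 26))          # p1 4 px, p2 6 px
  d <- plane_displacement(mv_annotation(pts), pixel_spacing = 1.0, rr_s = 1)
  expect_equal(d$values, c(0, 5, 5))

  deg <- array(1, c(2, 2, 2))
  expect_error(plane_displacement(mv_annotation(deg), 1, rr_s = 1), "degenerate")
  expect_warning(plane_displacement(mv_annotation(pts), 1), "RR")
})

test_that("displacement is invariant to rigid motion of the whole series and to units", {
  out <- quick_cine(seed = 7, n_frames = 14L, rotation = 25)
  ann <- out$annotation
  sp <- out$cine$pixel_spacing
  d0 <- plane_displacement(ann, sp, rr_s = 1)

  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- ann$points
  for (i in seq_len(dim(pts)[1])) for (j in 1:2)
    pts[i, j, ] <- as.numeric(R %*% pts[i, j, ]) + c(40, -12)
  d1 <- plane_displacement(mv_annotation(pts), sp, rr_s = 1)
  expect_equal(d1$values, d0$values, tolerance = 1e-9)

  # doubling the spacing with halved pixel coordinates changes nothing
  d2 <- plane_displacement(mv_annotation(ann$points / 2), sp * 2, rr_s = 1)
  expect_equal(d2$values, d0$values, tolerance = 1e-9)
})

test_that("resultant displacement averages and resamples between frame counts", {
  t10 <- seq(0, 1, length.out = 10)
  a <- displacement_curve(t10, rep(8, 10))
  b <- displacement_curve(t10, rep(12, 10))
  expect_equal(resultant_displacement(a, b)$values, rep(10, 10))
  expect_equal(resultant_displacement(a, a)$values, a$values)

  m <- motion_profile_params(mapse_mm = 12, n_frames = 30)
  m25 <- motion_profile_params(mapse_mm = 12, n_frames = 25)
  d30 <- generate_displacement_profile(m)
  d25 <- generate_displacement_profile(m25)
  res <- resultant_displacement(d30, d25)
  expect_length(res$values, 30L)
  ref <- (d30$values + approx(d25$times, d25$values, xout = d30$times)$y) / 2
  expect_lt(max(abs(res$values - d30$values)), 0.02 * 12)
  expect_equal(res$values, ref, tolerance = 1e-12)
})

test_that("velocity differentiation matches hand-computed differences", {
  d <- displacement_curve(seq(0, 0.4, by = 0.1), c(0, 5, 10, 5, 0))
  v <- velocity_curve(d)
  expect_equal(v$values[2:4], c(5, 0, -5))
  expect_equal(v$values[1], 5)   # one-sided endpoints
  expect_equal(v$values[5], -5)

  expect_equal(velocity_curve(displacement_curve(1:5 / 10, rep(3, 5)))$values,
               rep(0, 5))
  expect_error(velocity_curve(displacement_curve(c(0, 1), c(0, 1))), "3 samples")
  expect_error(velocity_curve(displacement_curve(c(0, 0.1, 0.35), c(0, 1, 2))),
               "uniform")

  # sampled sine: derivative peak within 2% at 30 samples/cycle
  tt <- seq(0, 1, length.out = 31)
  ds <- displacement_curve(tt, 7 * sin(2 * pi * tt))
  vs <- velocity_curve(ds)
  expect_lt(abs(max(abs(vs$values)) - 7 * 2 * pi / 10) / (7 * 2 * pi / 10), 0.02)
})

test_that("peak metrics recover the generating profile and its analytic derivatives", {
  p <- motion_profile_params(mapse_mm = 15, n_frames = 30)
  m <- derive_metrics(generate_displacement_profile(p))
  a <- analytic_velocity_peaks(p)
  expect_lt(abs(m$mapse_mm - 15) / 15, 0.01)
  expect_lt(abs(m$s_prime_cm_s - a$s_prime_cm_s) / a$s_prime_cm_s, 0.05)
  expect_lt(abs(m$e_prime_cm_s - a$e_prime_cm_s) / a$e_prime_cm_s, 0.05)
  expect_lt(abs(m$a_prime_cm_s - a$a_prime_cm_s) / a$a_prime_cm_s, 0.05)
  expect_true(m$complete)
})

test_that("peak labels obey the time-order invariant on generated profiles", {
  set.seed(51)
  for (i in 1:25) {
    p <- motion_profile_params(mapse_mm = runif(1, 8, 18),
                               hr_bpm = runif(1, 50, 90),
                               n_frames = sample(25:50, 1),
                               systole_fraction = runif(1, 0.32, 0.40),
                               diastasis_fraction = runif(1, 0.24, 0.32),
                               atrial_kick_fraction_of_mapse = runif(1, 0.18, 0.30))
    m <- derive_metrics(generate_displacement_profile(p))
    expect_true(m$complete)
    expect_lt(m$t_s_prime, m$t_mapse)
    expect_lte(m$t_mapse, m$t_e_prime)
    expect_lt(m$t_e_prime, m$t_a_prime)
  }
})

test_that("a single-phase return yields e-prime only, with a-prime flagged absent", {
  tt <- seq(0, 1, length.out = 40)
  vals <- ifelse(tt <= 0.35, 12 * (1 - cos(pi * tt / 0.35)) / 2,
                 12 * (1 + cos(pi * (tt - 0.35) / 0.65)) / 2)
  m <- derive_metrics(displacement_curve(tt, vals))
  expect_false(m$complete)
  expect_true(is.na(m$a_prime_cm_s))
  v <- velocity_curve(displacement_curve(tt, vals))
  mins <- oracle_extrema(v$values, minima = TRUE)
  mins <- mins[v$values[mins] < 0]
  expect_equal(m$e_prime_cm_s, abs(min(v$values[mins])), tolerance = 0.02)
})

test_that("two-frame annotations give MAPSE but no velocity metrics", {
  d <- displacement_curve(c(0, 0.4), c(0, 11))
  m <- derive_metrics(d)
  expect_equal(m$mapse_mm, 11)
  expect_false(m$complete)
  expect_true(is.na(m$e_prime_cm_s))
})
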