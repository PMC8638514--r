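# Shared fixture builders: everything is generated in code at test time.

# A small, fast phantom: coarse grid, few frames.
quick_motion <- function(n_frames = 12L, mapse_mm = 10, noise_sd = 0,
                         ...) {
  motion_profile_params(mapse_mm = mapse_mm, n_frames = n_frames,
                        noise_sd = noise_sd, ...)
}

quick_render <- function(image_size = c(96L, 96L), pixel_spacing_mm = 1.5,
                         annulus_width_mm = 28, ...) {
  render_params(image_size = image_size, pixel_spacing_mm = pixel_spacing_mm,
                annulus_width_mm = annulus_width_mm, ...)
}

quick_cine <- function(seed = 1L, n_frames = 12L, rotation = 0,
                       noise_sd = 0, ...) {
  render_cine(quick_motion(n_frames = n_frames, noise_sd = noise_sd),
              quick_render(heart_rotation_deg = rotation, ...), seed = seed)
}

# Independent brute-force two-way ANOVA mean squares (explicit sums over
# deviations, no shared code with the package) and the ICC(2,1) formula.
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_rows <- 0; ss_cols <- 0; ss_tot <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) ss_tot <- ss_tot + (m[i, j] - grand)^2
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Exhaustive local-extremum enumeration on a sampled curve (oracle for
# peak structure checks).
oracle_extrema <- function(v, minima = TRUE) {
  s <- if (minima) -v else v
  idx <- c()
  for (i in 2:(length(s) - 1)) {
    if (s[i] >= s[i - 1] && s[i] >= s[i + 1] &&
        (s[i] > s[i - 1] || s[i] > s[i + 1])) idx <- c(idx, i)
  }
  idx
}

# Train a throwaway micro regressor (for plumbing tests that just need a
# valid mv_regressor object).
micro_model <- function(input_size, seed = 1L) {
  img <- matrix(seq(0, 1, length.out = prod(input_size)), input_size[1])
  pts <- matrix(c(10, 12, 30, 12), 1L, 4L)
  cfg <- regressor_config("tiny", input_size, learning_rate = 1e-3,
                          n_epochs = 1L, batch_size = 2L,
                          augmentation_factor = 1L, seed = seed,
                          hidden = 16L, n_blocks = 1L)
  train_regressor(list(img, img), rbind(pts, pts), cfg)
}
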