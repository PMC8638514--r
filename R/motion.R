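## Synthetic mitral-valve plane motion: a piecewise cosine-ramp profile
## reproducing the four phases of longitudinal annular motion -- systolic
## descent towards the apex, early-diastolic recoil, diastasis plateau,
## and the late-diastolic atrial kick that completes the return.

# Share of the non-plateau diastole occupied by the early recoil; the
# remainder is the atrial kick.  Fixed so that e' exceeds a' with a
# physiological ratio (~1.3) at the default parameters.
RECOIL_SHARE <- 0.52

#' Motion profile parameters
#'
#' @param mapse_mm peak plane excursion towards the apex (mm).
#' @param hr_bpm heart rate; the RR interval is `60 / hr_bpm` seconds.
#' @param n_frames frames per cycle; frames span the full cycle with the
#'   first and last frame at the equilibrium plane.
#' @param systole_fraction fraction of the cycle elapsed at peak
#'   displacement.
#' @param diastasis_fraction fraction of diastole spent on the
#'   mid-diastolic plateau.
#' @param atrial_kick_fraction_of_mapse portion of the return to
#'   equilibrium completed by the atrial kick.
#' @param noise_sd additive image noise standard deviation, in intensity
#'   units of the rendered phantom (whose tissue values lie in [0, 1]).
#' @return an object of class `mv_motion_params`.
#' @export
motion_profile_params <- function(mapse_mm = 12, hr_bpm = 60, n_frames = 30L,
                                  systole_fraction = 0.35,
                                  diastasis_fraction = 0.28,
                                  atrial_kick_fraction_of_mapse = 0.25,
                                  noise_sd = 0.03) {
  if (!is.finite(mapse_mm) || mapse_mm < 0) stopf("mapse_mm must be >= 0")
  if (!is.finite(hr_bpm) || hr_bpm <= 0) stopf("hr_bpm must be positive")
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stopf("n_frames must be >= 2")
  fr <- c(systole_fraction, diastasis_fraction, atrial_kick_fraction_of_mapse)
  if (any(!is.finite(fr)) || any(fr <= 0) || any(fr >= 1))
    stopf("systole, diastasis and atrial-kick fractions must lie strictly in (0, 1)")
  if (!is.finite(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(mapse_mm = mapse_mm, hr_bpm = hr_bpm, n_frames = n_frames,
                 systole_fraction = systole_fraction,
                 diastasis_fraction = diastasis_fraction,
                 atrial_kick_fraction_of_mapse = atrial_kick_fraction_of_mapse,
                 noise_sd = noise_sd),
            class = "mv_motion_params")
}

## Phase boundaries as cycle fractions, snapped to the frame grid so the
## sampled curve attains its extrema exactly on frames.  Returns
## b = (end of descent, end of recoil, end of plateau) and the plateau
## level P = mapse * atrial_kick_fraction.
profile_breaks <- function(params) {
  n <- params$n_frames
  P <- params$mapse_mm * params$atrial_kick_fraction_of_mapse
  b1 <- params$systole_fraction
  D <- 1 - b1
  b2 <- b1 + D * (1 - params$diastasis_fraction) * RECOIL_SHARE
  b3 <- b2 + D * params$diastasis_fraction
  if (n >= 6L) {
    # snap phase boundaries to the frame grid so sampled extrema are exact;
    # below six frames the grid is too coarse to hold all four phases and
    # the continuous boundaries are sampled as-is
    h <- 1 / (n - 1)
    snap <- function(x) round(x * (n - 1)) / (n - 1)
    b1 <- min(max(snap(b1), h), 1 - 3 * h)
    D <- 1 - b1
    b2 <- min(max(snap(b1 + D * (1 - params$diastasis_fraction) * RECOIL_SHARE),
                  b1 + h), 1 - 2 * h)
    b3 <- min(max(snap(b2 + D * params$diastasis_fraction), b2), 1 - h)
  }
  list(b = c(b1, b2, b3), P = P)
}

## Continuous profile evaluated at cycle fractions phi in [0, 1].
profile_value <- function(phi, params, brk = profile_breaks(params)) {
  M <- params$mapse_mm; P <- brk$P; b <- brk$b
  ramp <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2
  out <- numeric(length(phi))
  i1 <- phi <= b[1]
  out[i1] <- M * ramp(phi[i1] / b[1])
  i2 <- phi > b[1] & phi <= b[2]
  out[i2] <- M - (M - P) * ramp((phi[i2] - b[1]) / (b[2] - b[1]))
  i3 <- phi > b[2] & phi <= b[3]
  out[i3] <- P
  i4 <- phi > b[3]
  out[i4] <- P * (1 - ramp((phi[i4] - b[3]) / (1 - b[3])))
  out
}

#' Generate the per-frame MV plane displacement profile
#'
#' Signed displacement in mm, positive towards the apex: zero at frame 0,
#' a single global maximum equal to `mapse_mm` at the frame nearest the
#' systolic fraction (phase boundaries are snapped to the frame grid so
#' the peak is attained exactly), a smooth biphasic return -- recoil,
#' diastasis plateau, atrial kick -- back to zero at cycle end.
#'
#' @param params an [motion_profile_params()] object.
#' @return an `mv_displacement` curve (see [displacement_curve()]).
#' @export
generate_displacement_profile <- function(params) {
  stopifnot(inherits(params, "mv_motion_params"))
  n <- params$n_frames
  phi <- seq(0, 1, length.out = n)
  rr <- 60 / params$hr_bpm
  displacement_curve(phi * rr, profile_value(phi, params))
}

#' Analytic velocity peaks of the synthetic profile
#'
#' Closed-form peak velocities of the piecewise cosine-ramp profile as
#' constructed (i.e. with phase boundaries snapped to the frame grid): a
#' half-cosine segment of amplitude `A` over `T` seconds has peak slope
#' `A * pi / (2 T)`.  Used as the independent reference when checking
#' velocities derived from sampled curves.
#'
#' @param params an [motion_profile_params()] object.
#' @return list with `s_prime_cm_s`, `e_prime_cm_s`, `a_prime_cm_s`
#'   (magnitudes) and their times in seconds.
#' @export
analytic_velocity_peaks <- function(params) {
  brk <- profile_breaks(params)
  b <- brk$b; M <- params$mapse_mm; P <- brk$P
  rr <- 60 / params$hr_bpm
  peak <- function(amp, len_frac) amp * pi / (2 * len_frac * rr) / 10  # mm/s -> cm/s
  list(s_prime_cm_s = peak(M, b[1]),
       e_prime_cm_s = peak(M - P, b[2] - b[1]),
       a_prime_cm_s = peak(P, 1 - b[3]),
       t_s_prime = b[1] / 2 * rr,
       t_e_prime = (b[1] + b[2]) / 2 * rr,
       t_a_prime = (b[3] + 1) / 2 * rr)
}
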