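## Clinical metric derivation: MV plane displacement and velocity curves,
## MAPSE and the three global longitudinal velocity peaks s', e', a'.

#' Displacement curve container
#'
#' Signed MV plane displacement over the cycle: mm, positive towards the
#' apex, zero at frame 0 (the end-diastolic reference plane).
#' @param times seconds from frame 0, strictly increasing.
#' @param values_mm displacement values, same length as `times`.
#' @param view optional label (`"2ch"`, `"4ch"` or `"resultant"`).
#' @return object of class `mv_displacement`.
#' @export
displacement_curve <- function(times, values_mm, view = NULL) {
  if (length(times) != length(values_mm))
    stopf("times and values must have equal length")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values_mm),
                 view = view), class = "mv_displacement")
}

#' Velocity curve container
#' @param times seconds from frame 0.
#' @param values_cm_s signed velocity in cm/s, positive towards the apex.
#' @return object of class `mv_velocity`.
#' @export
velocity_curve_obj <- function(times, values_cm_s) {
  structure(list(times = as.numeric(times), values = as.numeric(values_cm_s)),
            class = "mv_velocity")
}

## Signed perpendicular distances (px units of the plane normal in mm)
## of points to the infinite line through (p1, p2), in physical mm
## coordinates.  Positive on the `ref_side` of the line.
point_line_distance_mm <- function(pts_px, p1_px, p2_px, spacing) {
  a <- p1_px * spacing
  b <- p2_px * spacing
  d <- b - a
  nrm <- c(-d[2], d[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  (sweep(sweep(pts_px, 2, spacing, "*"), 2, a, "-")) %*% nrm
}

#' MV plane displacement from a time-resolved annotation
#'
#' For every frame, the signed perpendicular distances of both MV points
#' to the infinite line through the frame-0 points (the end-diastolic
#' reference plane, fixed for the whole cycle) are converted to mm via
#' the pixel spacing and averaged.  The sign is positive on the apex
#' side, determined -- as in the standardization -- as the side of the
#' reference plane carrying the largest perpendicular excursion.
#'
#' @param ann an `mv_annotation` with >= 2 frames; frame 0 must be
#'   end-diastole (the caller's contract).
#' @param pixel_spacing mm spacing `c(x, y)`; scalar recycled.
#' @param frame_times optional per-frame times in seconds.
#' @param rr_s cycle duration used to build uniform times when
#'   `frame_times` is absent; defaults to 1.0 s with a warning.
#' @return an `mv_displacement` curve.
#' @export
plane_displacement <- function(ann, pixel_spacing, frame_times = NULL,
                               rr_s = NULL) {
  n <- dim(ann$points)[1]
  if (n < 2L) stopf("plane displacement needs >= 2 annotated frames")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  f0 <- annotation_frame(ann, 0)
  if (sqrt(sum((f0[2, ] - f0[1, ])^2)) < 1e-12)
    stopf("degenerate reference plane: frame-0 points coincide")

  d1 <- point_line_distance_mm(ann$points[, 1, , drop = TRUE], f0[1, ], f0[2, ],
                               pixel_spacing)
  d2 <- point_line_distance_mm(ann$points[, 2, , drop = TRUE], f0[1, ], f0[2, ],
                               pixel_spacing)
  vals <- (d1 + d2) / 2

  # orient positive towards the apex: the side with the largest
  # perpendicular excursion (same rule as the standardization)
  later <- vals[-1]
  apex_stat <- later[which.max(abs(later))]
  if (is.finite(apex_stat) && apex_stat < 0) vals <- -vals

  if (is.null(frame_times)) {
    if (is.null(rr_s)) {
      warnf("no frame timing supplied; assuming an RR interval of 1.0 s")
      rr_s <- 1.0
    }
    frame_times <- seq(0, rr_s, length.out = n)
  }
  displacement_curve(frame_times, as.numeric(vals), view = ann$view)
}

#' Resultant displacement from the two chamber views
#'
#' Frame-wise mean of the two per-view curves; when the views were
#' reconstructed with different frame counts the shorter curve is first
#' interpolated linearly onto the longer's time base.
#'
#' @param c2ch,c4ch `mv_displacement` curves spanning one cycle.
#' @return an `mv_displacement` with view `"resultant"`.
#' @export
resultant_displacement <- function(c2ch, c4ch) {
  for (cc in list(c2ch, c4ch))
    if (!inherits(cc, "mv_displacement") || length(cc$values) < 2L)
      stopf("both inputs must be displacement curves with >= 2 samples")
  if (length(c2ch$times) < length(c4ch$times)) { tmp <- c2ch; c2ch <- c4ch; c4ch <- tmp }
  v_long <- c2ch$values
  v_short <- approx(c4ch$times, c4ch$values, xout = c2ch$times, rule = 2)$y
  displacement_curve(c2ch$times, (v_long + v_short) / 2, view = "resultant")
}

#' Velocity curve from a displacement curve
#'
#' Central differences at interior samples, one-sided differences at the
#' endpoints; mm/s converted to cm/s.  Requires >= 3 uniformly spaced,
#' strictly increasing time samples.
#'
#' @param d an `mv_displacement`.
#' @return an `mv_velocity`.
#' @export
velocity_curve <- function(d) {
  t <- d$times; v <- d$values
  n <- length(v)
  if (n < 3L) stopf("velocity needs >= 3 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stopf("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) stopf("times must be uniformly spaced")
  h <- mean(dt)
  vel <- numeric(n)
  vel[1] <- (v[2] - v[1]) / h
  vel[n] <- (v[n] - v[n - 1]) / h
  vel[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  velocity_curve_obj(t, vel / 10)
}

## Quadratic sub-sample refinement of a discrete extremum at index i
## (interior): fits a parabola through (i-1, i, i+1) and returns the
## refined extremal value and time.
refine_peak <- function(t, v, i) {
  n <- length(v)
  if (i <= 1L || i >= n) return(list(value = v[i], time = t[i]))
  y0 <- v[i - 1]; y1 <- v[i]; y2 <- v[i + 1]
  denom <- y0 - 2 * y1 + y2
  if (abs(denom) < 1e-300) return(list(value = v[i], time = t[i]))
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 0.5), -0.5)
  h <- t[2] - t[1]
  list(value = y1 - 0.25 * (y0 - y2) * delta, time = t[i] + delta * h)
}

## indices of local minima of v (strictly lower than at least one
## neighbour, not higher than either), interior points only
local_extrema <- function(v, minima = TRUE) {
  if (minima) v <- -v
  n <- length(v)
  if (n < 3L) return(integer())
  idx <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
                 (v[2:(n - 1)] > v[1:(n - 2)] | v[2:(n - 1)] > v[3:n])) + 1L
  idx
}

#' Derive MAPSE and the global velocity peaks s', e', a'
#'
#' MAPSE is the maximal plane displacement.  The velocity peaks are
#' resolved in time order with phase gating: s' is the apex-directed
#' velocity peak before the MAPSE time (first global peak), e' the
#' largest-magnitude return-directed velocity peak after the MAPSE time
#' (second global peak) and a' the largest-magnitude return-directed peak
#' after e' (third global peak).  Return-directed peaks are local minima
#' of the signed velocity and are reported as positive magnitudes.
#' Discrete peaks are refined by quadratic interpolation of the three
#' neighbouring samples.  Annotations with only two frames (end-diastole
#' and end-systole) yield MAPSE with the velocity metrics flagged
#' unavailable.
#'
#' @param d an `mv_displacement` covering one full cycle.
#' @param v optionally its `mv_velocity`; computed when `NULL`.
#' @return an object of class `mv_clinical_metrics`: a list with
#'   `mapse_mm`, `s_prime_cm_s`, `e_prime_cm_s`, `a_prime_cm_s`, their
#'   peak times, and a `complete` flag.
#' @export
derive_metrics <- function(d, v = NULL) {
  imax <- which.max(d$values)
  mapse <- d$values[imax]
  t_mapse <- d$times[imax]

  res <- list(mapse_mm = mapse, t_mapse = t_mapse,
              s_prime_cm_s = NA_real_, t_s_prime = NA_real_,
              e_prime_cm_s = NA_real_, t_e_prime = NA_real_,
              a_prime_cm_s = NA_real_, t_a_prime = NA_real_,
              complete = FALSE)
  if (length(d$values) < 3L) {
    class(res) <- "mv_clinical_metrics"
    return(res)
  }
  if (is.null(v)) v <- velocity_curve(d)

  # s': extremal apex-directed velocity before the MAPSE time
  pre <- which(v$times <= t_mapse)
  if (length(pre)) {
    is <- pre[which.max(v$values[pre])]
    pks <- refine_peak(v$times, v$values, is)
    res$s_prime_cm_s <- abs(pks$value)
    res$t_s_prime <- pks$time
  }

  # e', a': return-directed (negative) local minima after the MAPSE time
  post <- which(v$times >= t_mapse)
  mins <- local_extrema(v$values, minima = TRUE)
  mins <- mins[mins %in% post & v$values[mins] < 0]
  # a flat-bottomed lobe yields adjacent tied minima: one candidate per lobe
  if (length(mins)) mins <- mins[c(TRUE, diff(mins) > 1L)]
  if (length(mins)) {
    ie <- mins[which.min(v$values[mins])]
    pke <- refine_peak(v$times, v$values, ie)
    res$e_prime_cm_s <- abs(pke$value)
    res$t_e_prime <- pke$time
    after <- mins[mins > ie]
    if (length(after)) {
      ia <- after[which.min(v$values[after])]
      pka <- refine_peak(v$times, v$values, ia)
      res$a_prime_cm_s <- abs(pka$value)
      res$t_a_prime <- pka$time
    }
  }
  res$complete <- all(is.finite(c(res$s_prime_cm_s, res$e_prime_cm_s,
                                  res$a_prime_cm_s)))
  class(res) <- "mv_clinical_metrics"
  res
}

#' @export
print.mv_clinical_metrics <- function(x, ...) {
  cat(sprintf("<mv_clinical_metrics> MAPSE %.2f mm; s' %.2f, e' %.2f, a' %.2f cm/s%s\n",
              x$mapse_mm, x$s_prime_cm_s, x$e_prime_cm_s, x$a_prime_cm_s,
              if (x$complete) "" else " (incomplete)"))
  invisible(x)
}

#' Clinical metrics for one subject from both chamber views
#'
#' Convenience wrapper: per-view plane displacement, resultant curve,
#' velocity, and peak metrics.
#'
#' @param ann2ch,ann4ch per-view `mv_annotation`s.
#' @param spacing2ch,spacing4ch per-view pixel spacings (mm).
#' @param rr_s RR interval in seconds.
#' @return an `mv_clinical_metrics` object with the resultant curves
#'   attached as attributes `displacement` and `velocity`.
#' @export
subject_metrics <- function(ann2ch, ann4ch, spacing2ch, spacing4ch, rr_s) {
  d2 <- plane_displacement(ann2ch, spacing2ch, rr_s = rr_s)
  d4 <- plane_displacement(ann4ch, spacing4ch, rr_s = rr_s)
  dres <- resultant_displacement(d2, d4)
  m <- derive_metrics(dres)
  attr(m, "displacement") <- dres
  attr(m, "velocity") <- if (length(dres$values) >= 3) velocity_curve(dres) else NULL
  m
}
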