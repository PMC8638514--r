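## Agreement evaluation: the three spatial error metrics (Euclidean,
## angular, per-frame plane displacement) and the clinical-agreement
## statistics (ICC(2,1) with 95% CI, Bland-Altman, linear regression),
## plus the stage-wise comparison harness.

#' Per-point Euclidean annotation error in mm
#'
#' Straight-line distance between matched points of two annotations of
#' the same frames, using the anisotropic pixel spacing
#' (`sqrt((dx * sx)^2 + (dy * sy)^2)`).  Point labels are matched
#' positionally (anterior to anterior, etc.), never permuted.
#'
#' @param pred,gt `mv_annotation`s covering identical frames.
#' @param pixel_spacing mm spacing `c(x, y)`; scalar recycled.
#' @return `n_frames x 2` matrix of errors (mm), columns = points.
#' @export
euclidean_error <- function(pred, gt, pixel_spacing) {
  np <- dim(pred$points)[1]; ng <- dim(gt$points)[1]
  if (np != ng)
    stopf("annotations cover different frames: pred has %d, gt has %d", np, ng)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  dx <- (pred$points[, , 1] - gt$points[, , 1]) * pixel_spacing[1]
  dy <- (pred$points[, , 2] - gt$points[, , 2]) * pixel_spacing[2]
  e <- sqrt(dx^2 + dy^2)
  colnames(e) <- gt$labels
  e
}

#' Per-frame angular error between annotated valve planes
#'
#' The acute ("inner") intersection angle, in degrees, between the two
#' lines defined by each annotation's point pair, measured in physical
#' (mm-scaled) coordinates; range [0, 90].  Frames where either
#' annotation's points coincide are flagged `NA` and should be excluded
#' listwise from summaries.
#'
#' @param pred,gt `mv_annotation`s covering identical frames.
#' @param pixel_spacing mm spacing `c(x, y)`; scalar recycled.
#' @return numeric vector of per-frame angles in degrees.
#' @export
angular_error <- function(pred, gt, pixel_spacing = c(1, 1)) {
  np <- dim(pred$points)[1]
  if (np != dim(gt$points)[1]) stopf("annotations cover different frames")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  ang <- function(ann) {
    dx <- (ann$points[, 2, 1] - ann$points[, 1, 1]) * pixel_spacing[1]
    dy <- (ann$points[, 2, 2] - ann$points[, 1, 2]) * pixel_spacing[2]
    cbind(dx, dy)
  }
  a <- ang(pred); b <- ang(gt)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  bad <- na < 1e-12 | nb < 1e-12
  cosang <- abs(rowSums(a * b)) / (na * nb)
  out <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  out[bad] <- NA_real_
  out
}

#' Per-frame MV plane displacement error
#'
#' Signed difference `pred - gt` between two displacement curves on the
#' same time base; its mean +- sd is the displacement-agreement summary.
#' Point offsets along the valve plane leave this metric untouched, which
#' is why tracking the plane's motion is more reproducible than tracking
#' each point's location.
#'
#' @param pred_curve,gt_curve `mv_displacement` curves of equal length.
#' @return numeric vector of per-frame signed errors (mm).
#' @export
displacement_error <- function(pred_curve, gt_curve) {
  if (length(pred_curve$values) != length(gt_curve$values))
    stopf("curves have different lengths")
  pred_curve$values - gt_curve$values
}

## Two-way ANOVA mean squares of an n x k ratings table.
anova_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects model, absolute agreement, single measures,
#' with the 95% confidence interval from the standard F-distribution
#' bounds (McGraw & Wong's ICC(A,1)).
#'
#' @param x,y paired measurements (>= 3 finite pairs).
#' @param conf confidence level, default 0.95.
#' @return list with `icc`, `ci` (length 2), `n` and the ANOVA mean
#'   squares used.
#' @export
icc_agreement <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  m <- cbind(x[ok], y[ok])
  n <- nrow(m); k <- 2L
  if (n < 3L) stopf("ICC needs >= 3 complete pairs")
  ms <- anova_mean_squares(m)
  if (ms$msr + ms$msc + ms$mse < 1e-300)
    stopf("undefined ICC: zero total variance")
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)

  # F-based confidence bounds (Satterthwaite df for the rater term)
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (ms$msr - f_l * ms$mse) /
    (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (f_u * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
  list(icc = icc, ci = c(lower, upper), n = n, mean_squares = ms)
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is `mean(y - x)`; the limits of agreement are
#' `bias +- 1.96 * sd(y - x)`.
#'
#' @param x,y paired measurements (>= 2 finite pairs).
#' @return list with `bias`, `loa` (lower, upper), `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- (y - x)[ok]
  if (length(d) < 2L) stopf("Bland-Altman needs >= 2 complete pairs")
  bias <- mean(d); s <- sd(d)
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       sd_diff = s, n = length(d))
}

#' Full agreement statistics between two raters/methods
#'
#' ICC(2,1) with CI, Bland-Altman bias and limits, and ordinary linear
#' regression of `y` on `x`.
#' @param x,y paired measurements.
#' @return list of class `mv_agreement` with components `icc`, `ba`,
#'   `regression` (slope, intercept, r) and `n`.
#' @export
agreement_stats <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  icc <- icc_agreement(x[ok], y[ok])
  ba <- bland_altman(x[ok], y[ok])
  fit <- lm(y[ok] ~ x[ok])
  r <- suppressWarnings(stats::cor(x[ok], y[ok]))
  structure(list(icc = icc, ba = ba,
                 regression = list(slope = unname(coef(fit)[2]),
                                   intercept = unname(coef(fit)[1]), r = r),
                 n = sum(ok)),
            class = "mv_agreement")
}

#' @export
print.mv_agreement <- function(x, ...) {
  cat(sprintf("<mv_agreement> n=%d ICC %.3f (%.3f-%.3f), bias %.3g, LoA [%.3g, %.3g], slope %.3f, r %.3f\n",
              x$n, x$icc$icc, x$icc$ci[1], x$icc$ci[2], x$ba$bias,
              x$ba$loa[1], x$ba$loa[2], x$regression$slope, x$regression$r))
  invisible(x)
}

#' Stage-wise agreement report
#'
#' Pools all spatial agreement metrics per pipeline stage over a set of
#' tracked cines, and -- when at least three subjects are available --
#' adds the clinical MAPSE agreement (ICC against ground truth).  Frames
#' flagged degenerate in the angular metric are excluded listwise, with
#' counts reported.
#'
#' @param results list of `mv_tracking` objects.
#' @param gts matching list of ground-truth `mv_annotation`s.
#' @param spacings list (or single value) of per-cine pixel spacings, mm.
#' @param rr_s list or vector of per-cine RR intervals, seconds
#'   (default 1).
#' @return data.frame with one row per stage: mean/sd of the Euclidean,
#'   angular and displacement errors, excluded-frame count, MAPSE ICC and
#'   its CI (NA when too few subjects).
#' @export
stagewise_report <- function(results, gts, spacings, rr_s = 1) {
  if (length(results) == 0L) stopf("no tracking results supplied")
  if (length(results) != length(gts)) stopf("results and gts differ in length")
  nres <- length(results)
  if (!is.list(spacings)) spacings <- rep(list(spacings), nres)
  if (length(rr_s) == 1L) rr_s <- rep(rr_s, nres)
  stage_names <- names(results[[1]]$stages)

  rows <- lapply(stage_names, function(st) {
    eu <- c(); an <- c(); de <- c(); mapse_p <- c(); mapse_g <- c(); nexcl <- 0L
    for (i in seq_len(nres)) {
      pred <- results[[i]]$stages[[st]]
      gt <- gts[[i]]
      sp <- spacings[[i]]
      eu <- c(eu, euclidean_error(pred, gt, sp))
      ai <- angular_error(pred, gt, sp)
      nexcl <- nexcl + sum(!is.finite(ai))
      an <- c(an, ai[is.finite(ai)])
      dp <- plane_displacement(pred, sp, rr_s = rr_s[i])
      dg <- plane_displacement(gt, sp, rr_s = rr_s[i])
      de <- c(de, displacement_error(dp, dg))
      mapse_p <- c(mapse_p, max(dp$values))
      mapse_g <- c(mapse_g, max(dg$values))
    }
    icc <- if (nres >= 3L && var(mapse_g) > 0)
      tryCatch(icc_agreement(mapse_g, mapse_p), error = function(e) NULL) else NULL
    data.frame(stage = st,
               euclid_mean_mm = mean(eu), euclid_sd_mm = sd(eu),
               angular_mean_deg = mean(an), angular_sd_deg = sd(an),
               disp_err_mean_mm = mean(de), disp_err_sd_mm = sd(de),
               frames_excluded = nexcl,
               mapse_icc = if (is.null(icc)) NA_real_ else icc$icc,
               mapse_icc_lo = if (is.null(icc)) NA_real_ else icc$ci[1],
               mapse_icc_hi = if (is.null(icc)) NA_real_ else icc$ci[2])
  })
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(icc_variant = "ICC(2,1) absolute agreement",
                                loa_sd = "sample sd",
                                n_cines = nres)
  out
}

#' Write a stage-wise report as CSV and JSON
#' @param report data.frame from [stagewise_report()].
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv))
    write_atomic(path_csv, function(p) write.csv(report, p, row.names = FALSE))
  if (!is.null(path_json))
    write_atomic(path_json, function(p)
      jsonlite::write_json(list(metadata = attr(report, "metadata"),
                                stages = report),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  invisible(report)
}
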