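## Dual-stage inference per cine and view: coarse pass on the fixed
## 160x160 grid, automated standardization, refined pass on the standard
## grid, exact inverse mapping, optional iteration of the refinement.

#' Coarse stage-1 annotation of a cine
#'
#' Resizes every frame to the coarse network grid (160 x 160, cubic),
#' predicts the two MV points per frame, and maps the predictions back to
#' the original grid through the exact inverse of the resize transform.
#'
#' @param cine an `mv_cine`.
#' @param model a trained `mv_regressor` for the coarse grid (or an
#'   [oracle_regressor()]).
#' @param size the coarse grid, default `c(160, 160)`.
#' @return an `mv_annotation` in original image coordinates.
#' @export
stage1_coarse <- function(cine, model, size = c(160L, 160L)) {
  rs <- resize_to_network_grid(cine, size)
  n <- n_frames(cine)
  pts <- matrix(NA_real_, n, 4L)
  for (i in seq_len(n)) {
    pts[i, ] <- predict_points(model, rs$cine$frames[, , i],
                               frame = i - 1L, transform = rs$transform)
  }
  inv <- invert_transform(rs$transform, output_size = dim(cine$frames)[1:2])
  ann <- mv_annotation(pts, view = cine$view)
  map_annotation(ann, inv, "forward")
}

#' Refined stage-2 annotation of a cine
#'
#' Estimates the automated standardization from the current annotation,
#' standardizes the cine (0.75 mm, horizontal valve, apex down, 118 x 162
#' crop), predicts on every standardized frame, and maps the predictions
#' back to the original grid.
#'
#' @param cine an `mv_cine`.
#' @param current the current `mv_annotation` (>= 2 frames).
#' @param model a trained `mv_regressor` for the standard grid (or an
#'   [oracle_regressor()]).
#' @return list with `annotation` (refined, original grid) and
#'   `transform` (the standardization used).
#' @export
stage2_refine <- function(cine, current, model) {
  t <- estimate_standardization(current, cine)
  std <- apply_transform(cine, t)
  n <- n_frames(cine)
  pts <- matrix(NA_real_, n, 4L)
  for (i in seq_len(n)) {
    pts[i, ] <- predict_points(model, std$cine$frames[, , i],
                               frame = i - 1L, transform = t)
  }
  inv <- invert_transform(t, output_size = dim(cine$frames)[1:2])
  ann <- map_annotation(mv_annotation(pts, view = cine$view), inv, "forward")
  list(annotation = ann, transform = t)
}

#' Track the MV points through the dual-stage pipeline
#'
#' Runs the coarse pass, then `n_refine` successive refinement passes,
#' re-estimating the standardization from the most recent annotation
#' before each pass.  The default `n_refine = 2` runs the refinement and
#' one iteration of it (the "stage 1+2+2" configuration); accuracy does
#' not improve beyond one iteration.  A refinement pass that fails --
#' either by raising an error (degenerate intermediate annotation) or by
#' producing an implausible result (mean point movement relative to its
#' input beyond `consistency_limit_mm`, the signature of a standardization
#' built from an uninformative coarse annotation) -- falls back to the
#' last successful stage with a warning, so batch runs never abort or
#' derail on one cine.
#'
#' @param cine an `mv_cine`.
#' @param stage1_model regressor for the coarse 160 x 160 grid.
#' @param stage2_model regressor for the standardized 118 x 162 grid.
#' @param n_refine number of refinement passes (>= 0).
#' @param reestimate re-estimate the standardization from the latest
#'   annotation at each pass (default); `FALSE` reuses the first
#'   estimated transform.
#' @param consistency_limit_mm reject a refinement pass whose mean point
#'   movement exceeds this; a legitimate correction is bounded by the
#'   coarse stage's own error, so the default 15 mm only triggers on
#'   divergence.  `Inf` disables the guard.
#' @return an object of class `mv_tracking`: per-stage annotations in
#'   original coordinates (named `stage1`, `stage1+2`, `stage1+2+2`, ...),
#'   the transforms used per refinement pass, and the view label.
#' @export
track_mv <- function(cine, stage1_model, stage2_model, n_refine = 2L,
                     reestimate = TRUE, consistency_limit_mm = 15) {
  if (n_refine < 0L) stopf("n_refine must be >= 0")
  stages <- list(stage1 = stage1_coarse(cine, stage1_model))
  transforms <- list()
  current <- stages$stage1
  name <- "stage1"
  t_prev <- NULL
  for (k in seq_len(n_refine)) {
    name <- paste0(name, "+2")
    res <- tryCatch({
      if (reestimate || is.null(t_prev)) {
        stage2_refine(cine, current, stage2_model)
      } else {
        std <- apply_transform(cine, t_prev)
        n <- n_frames(cine)
        pts <- matrix(NA_real_, n, 4L)
        for (i in seq_len(n))
          pts[i, ] <- predict_points(stage2_model, std$cine$frames[, , i],
                                     frame = i - 1L, transform = t_prev)
        inv <- invert_transform(t_prev, output_size = dim(cine$frames)[1:2])
        list(annotation = map_annotation(mv_annotation(pts, view = cine$view),
                                         inv, "forward"),
             transform = t_prev)
      }
    }, error = function(e) {
      warnf("refinement pass %d failed (%s); keeping previous stage", k,
            conditionMessage(e))
      NULL
    })
    if (!is.null(res) && is.finite(consistency_limit_mm)) {
      move <- mean(euclidean_error(res$annotation, current, cine$pixel_spacing))
      if (move > consistency_limit_mm) {
        warnf("refinement pass %d moved the annotation %.1f mm on average (> %.0f mm); keeping previous stage",
              k, move, consistency_limit_mm)
        res <- NULL
      }
    }
    if (is.null(res)) {
      stages[[name]] <- current
    } else {
      stages[[name]] <- res$annotation
      transforms[[name]] <- res$transform
      current <- res$annotation
      t_prev <- res$transform
    }
  }
  structure(list(stages = stages, transforms = transforms, view = cine$view),
            class = "mv_tracking")
}

#' @export
print.mv_tracking <- function(x, ...) {
  cat(sprintf("<mv_tracking> stages: %s (%d frames%s)\n",
              paste(names(x$stages), collapse = ", "),
              dim(x$stages[[1]]$points)[1],
              if (is.null(x$view)) "" else paste0(", view ", x$view)))
  invisible(x)
}
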