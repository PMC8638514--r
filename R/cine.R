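#' Cine image series
#'
#' Container for one view's time-resolved grayscale image stack together
#' with its geometry and timing metadata.  The coordinate convention used
#' throughout the package is 0-based with `x` the column index, `y` the
#' row index, pixel centres at integer coordinates and the origin at the
#' top-left pixel centre.
#'
#' @param frames numeric array `rows x cols x n_frames` (a single matrix
#'   is accepted and treated as one frame).
#' @param pixel_spacing in-plane pixel spacing in mm, length 2 `c(x, y)`
#'   (column spacing, row spacing); a scalar is recycled (isotropic).
#' @param rr_s duration in seconds of the cardiac cycle spanned by the
#'   frames; frame `i` is assigned time `i/(n-1) * rr_s` so the first and
#'   last frames bracket one full cycle.
#' @param view optional view label, `"2ch"` or `"4ch"`.
#' @param meta optional list of free-form metadata.
#' @return An object of class `mv_cine`.
#' @export
cine_series <- function(frames, pixel_spacing = c(1, 1), rr_s = 1,
                        view = NULL, meta = list()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L)
    stopf("frames must be a rows x cols x n_frames array")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stopf("pixel_spacing must be positive and finite")
  if (!is.null(view)) view <- match.arg(view, c("2ch", "4ch"))
  structure(list(frames = frames,
                 pixel_spacing = as.numeric(pixel_spacing[1:2]),
                 rr_s = as.numeric(rr_s), view = view, meta = meta),
            class = "mv_cine")
}

#' @export
print.mv_cine <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<mv_cine> %d x %d px, %d frames, spacing %.3g x %.3g mm, RR %.3g s%s\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2], x$rr_s,
              if (is.null(x$view)) "" else paste0(", view ", x$view)))
  invisible(x)
}

#' Number of frames in a cine or annotation
#' @param x an `mv_cine` or `mv_annotation`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "mv_cine")) return(dim(x$frames)[3])
  if (inherits(x, "mv_annotation")) return(dim(x$points)[1])
  stopf("n_frames() expects an mv_cine or mv_annotation")
}

#' Frame acquisition times
#'
#' Times in seconds from frame 0, spaced uniformly so the frames span one
#' RR interval inclusive of both ends.
#' @param x an `mv_cine`.
#' @return numeric vector of length `n_frames(x)`.
#' @export
frame_times <- function(x) {
  n <- n_frames(x)
  if (n == 1L) return(0)
  seq(0, x$rr_s, length.out = n)
}

#' Point labels conventionally attached to a view
#'
#' Two-chamber views carry the anterior and inferior insertion points,
#' four-chamber views the lateral and septal points; the first label is
#' the point placed on the left after standardization.
#' @param view `"2ch"` or `"4ch"`.
#' @return character vector of length 2.
#' @export
view_labels <- function(view) {
  switch(match.arg(view, c("2ch", "4ch")),
         "2ch" = c("anterior", "inferior"),
         "4ch" = c("lateral", "septal"))
}

#' Mitral valve point annotation
#'
#' Per-frame pair of MV insertion points in continuous (sub-pixel) image
#' coordinates of the original grid.
#'
#' @param points numeric array `n_frames x 2 x 2`, indexed
#'   `[frame, point, coordinate]` with coordinates ordered `(x, y)`.
#'   A matrix `n_frames x 4` ordered `(x1, y1, x2, y2)` is also accepted.
#' @param labels character vector of two point labels; defaults to the
#'   view's conventional labels when `view` is given.
#' @param view optional `"2ch"` or `"4ch"`.
#' @return An object of class `mv_annotation`.
#' @export
mv_annotation <- function(points, labels = NULL, view = NULL) {
  if (is.matrix(points) && ncol(points) == 4L) {
    points <- array(points[, c(1, 3, 2, 4), drop = FALSE],
                    c(nrow(points), 2L, 2L))
  }
  if (length(dim(points)) != 3L || dim(points)[2] != 2L || dim(points)[3] != 2L)
    stopf("points must be an n_frames x 2 x 2 array [frame, point, (x, y)]")
  if (any(!is.finite(points))) stopf("annotation coordinates must be finite")
  if (!is.null(view)) view <- match.arg(view, c("2ch", "4ch"))
  if (is.null(labels)) labels <- if (!is.null(view)) view_labels(view) else c("p1", "p2")
  if (length(labels) != 2L) stopf("labels must have length 2")
  structure(list(points = points, labels = as.character(labels), view = view),
            class = "mv_annotation")
}

#' @export
print.mv_annotation <- function(x, ...) {
  cat(sprintf("<mv_annotation> %d frames, points %s/%s%s\n",
              dim(x$points)[1], x$labels[1], x$labels[2],
              if (is.null(x$view)) "" else paste0(", view ", x$view)))
  invisible(x)
}

#' Extract one frame's point pair
#' @param ann an `mv_annotation`.
#' @param frame 0-based frame index.
#' @return 2 x 2 matrix, rows = points (in label order), columns `(x, y)`.
#' @export
annotation_frame <- function(ann, frame) {
  n <- dim(ann$points)[1]
  if (frame < 0 || frame >= n) stopf("frame %d outside 0..%d", frame, n - 1L)
  m <- ann$points[frame + 1L, , , drop = TRUE]
  dim(m) <- c(2L, 2L)
  colnames(m) <- c("x", "y")
  rownames(m) <- ann$labels
  m
}

#' Flatten an annotation to an n x 4 coordinate matrix
#' @param ann an `mv_annotation`.
#' @return matrix with columns `x1, y1, x2, y2`.
#' @export
annotation_matrix <- function(ann) {
  m <- cbind(ann$points[, 1, 1], ann$points[, 1, 2],
             ann$points[, 2, 1], ann$points[, 2, 2])
  colnames(m) <- c("x1", "y1", "x2", "y2")
  m
}

#' Per-frame midpoints of the annotated valve segment
#' @param ann an `mv_annotation`.
#' @return n x 2 matrix of `(x, y)` midpoints.
#' @export
annotation_midpoints <- function(ann) {
  cbind((ann$points[, 1, 1] + ann$points[, 2, 1]) / 2,
        (ann$points[, 1, 2] + ann$points[, 2, 2]) / 2)
}
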