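## Geometry: exactly invertible similarity transforms between image grids,
## the stage-1 resize and the stage-2 automated standardization.

#' Similarity transform between image grids
#'
#' Maps continuous 0-based pixel coordinates `(x, y)` (x = column,
#' y = row, pixel centres at integers) of an input grid onto an output
#' grid as
#' \deqn{p' = R(\theta)\,\mathrm{diag}(s)\,(p - \mathrm{pivot}) + t}
#' with per-axis scale `s` (output px per input px; may be anisotropic),
#' rotation `theta` (degrees, positive rotating +x towards +y, i.e.
#' clockwise on screen with y pointing down) and translation `t` in
#' output-grid pixels.
#'
#' @param scale length-2 positive scale `c(sx, sy)`; scalar recycled.
#' @param rotation_deg rotation angle in degrees.
#' @param translation length-2 output-grid offset `c(tx, ty)`.
#' @param pivot length-2 input-grid pivot point.
#' @param output_size optional output grid size `c(rows, cols)`.
#' @return An object of class `mv_transform` holding the 2x3 affine
#'   matrix together with its defining parameters.
#' @export
similarity_transform <- function(scale = c(1, 1), rotation_deg = 0,
                                 translation = c(0, 0), pivot = c(0, 0),
                                 output_size = NULL) {
  if (length(scale) == 1L) scale <- rep(scale, 2L)
  if (any(!is.finite(scale)) || any(scale <= 0))
    stopf("scale components must be positive and finite")
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  L <- R %*% diag(scale)
  t3 <- as.numeric(translation) - L %*% as.numeric(pivot)
  m <- cbind(L, t3)
  new_transform(m, output_size,
                scale = as.numeric(scale), rotation_deg = rotation_deg,
                translation = as.numeric(translation), pivot = as.numeric(pivot))
}

new_transform <- function(matrix2x3, output_size = NULL, scale = NULL,
                          rotation_deg = NULL, translation = NULL,
                          pivot = NULL) {
  stopifnot(is.matrix(matrix2x3), nrow(matrix2x3) == 2L, ncol(matrix2x3) == 3L)
  structure(list(matrix = matrix2x3,
                 output_size = if (is.null(output_size)) NULL else as.integer(output_size),
                 scale = scale, rotation_deg = rotation_deg,
                 translation = translation, pivot = pivot),
            class = "mv_transform")
}

#' @export
print.mv_transform <- function(x, ...) {
  d <- decompose_transform(x)
  if (!is.null(d))
    cat(sprintf("<mv_transform> scale (%.4g, %.4g), rotation %.4g deg, translation (%.4g, %.4g)%s\n",
                d$scale[1], d$scale[2], d$rotation_deg, d$translation[1], d$translation[2],
                if (is.null(x$output_size)) "" else
                  sprintf(", output %d x %d", x$output_size[1], x$output_size[2])))
  else cat("<mv_transform> general affine\n")
  invisible(x)
}

#' Decompose a transform into scale / rotation / translation
#'
#' Returns `NULL` when the linear part is not of the
#' rotation-times-positive-diagonal form.
#' @param t an `mv_transform`.
#' @return list with `scale`, `rotation_deg`, `translation`, or `NULL`.
#' @export
decompose_transform <- function(t) {
  L <- t$matrix[, 1:2]
  s1 <- sqrt(sum(L[, 1]^2))
  s2 <- sqrt(sum(L[, 2]^2))
  if (s1 == 0 || s2 == 0) return(NULL)
  th <- atan2(L[2, 1], L[1, 1])
  # check column 2 is consistent with a pure rotation of diag(s)
  expect2 <- c(-sin(th), cos(th)) * s2
  if (max(abs(L[, 2] - expect2)) > 1e-9 * max(1, s2)) return(NULL)
  list(scale = c(s1, s2), rotation_deg = th * 180 / pi,
       translation = as.numeric(t$matrix[, 3]))
}

full_matrix <- function(t) rbind(t$matrix, c(0, 0, 1))

#' Invert a transform
#' @param t an `mv_transform`.
#' @param output_size optional grid size of the inverse's output (the
#'   original input grid), `c(rows, cols)`.
#' @return the inverse `mv_transform`.
#' @export
invert_transform <- function(t, output_size = NULL) {
  Mi <- solve(full_matrix(t))
  new_transform(Mi[1:2, , drop = FALSE], output_size)
}

#' Compose two transforms
#'
#' `compose_transforms(outer, inner)` maps points first through `inner`
#' then through `outer`; the result equals the product of the two affine
#' matrices.
#' @param outer,inner `mv_transform` objects.
#' @return the composed `mv_transform` (output grid of `outer`).
#' @export
compose_transforms <- function(outer, inner) {
  M <- full_matrix(outer) %*% full_matrix(inner)
  new_transform(M[1:2, , drop = FALSE], outer$output_size)
}

#' Map continuous points through a transform
#'
#' Exact affine mapping of point coordinates; `inverse` followed by
#' `forward` (or vice versa) is the identity to better than 1e-9 px.
#'
#' @param points numeric `n x 2` matrix of `(x, y)` coordinates (a
#'   length-2 vector is treated as one point).
#' @param t an `mv_transform`.
#' @param direction `"forward"` (input grid to output grid) or
#'   `"inverse"`.
#' @return `n x 2` matrix of mapped coordinates.
#' @export
map_points <- function(points, t, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  if (any(!is.finite(points))) stopf("point coordinates must be finite")
  M <- t$matrix
  if (direction == "inverse") M <- solve(full_matrix(t))[1:2, , drop = FALSE]
  out <- points %*% t(M[, 1:2]) +
    matrix(M[, 3], nrow(points), 2L, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

#' Map a whole annotation through a transform
#' @param ann an `mv_annotation`.
#' @param t an `mv_transform`.
#' @param direction `"forward"` or `"inverse"`.
#' @return a new `mv_annotation` on the target grid.
#' @export
map_annotation <- function(ann, t, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  m <- annotation_matrix(ann)
  p1 <- map_points(m[, 1:2, drop = FALSE], t, direction)
  p2 <- map_points(m[, 3:4, drop = FALSE], t, direction)
  mv_annotation(cbind(p1[, 1], p1[, 2], p2[, 1], p2[, 2]),
                labels = ann$labels, view = ann$view)
}

interp_code <- function(interp) {
  switch(match.arg(interp, c("cubic", "bilinear", "nearest")),
         nearest = 0L, bilinear = 1L, cubic = 2L)
}

## Resample an image stack under a transform (inverse mapping + kernel).
resample_frames <- function(frames, t, out_size, interp = "cubic") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  Minv <- solve(full_matrix(t))[1:2, , drop = FALSE]
  resample_affine_cpp(frames, dim(frames), as.integer(out_size),
                      Minv, interp_code(interp))
}

#' Resize a cine onto the fixed coarse-stage network grid
#'
#' Resamples every frame to `size` (default 160 x 160) with cubic
#' interpolation, regardless of aspect ratio, so pixels may become
#' anisotropic.  The returned transform maps original-grid points onto
#' the resized grid (`x' = x * out_cols / in_cols`, likewise for y) and
#' is exactly invertible.
#'
#' @param cine an `mv_cine`.
#' @param size output grid `c(rows, cols)`.
#' @return list with elements `cine` (resized `mv_cine`) and `transform`.
#' @export
resize_to_network_grid <- function(cine, size = c(160L, 160L)) {
  d <- dim(cine$frames)
  if (d[1] <= 1L || d[2] <= 1L) stopf("degenerate input image (%d x %d)", d[1], d[2])
  size <- as.integer(size)
  sc <- c(size[2] / d[2], size[1] / d[1])  # (x, y)
  t <- similarity_transform(scale = sc, output_size = size)
  if (all(sc == 1)) {
    out <- cine$frames
  } else {
    out <- resample_frames(cine$frames, t, size, "cubic")
  }
  new_spacing <- cine$pixel_spacing / sc
  list(cine = cine_series(out, new_spacing, cine$rr_s, cine$view, cine$meta),
       transform = t)
}

#' Standard output grid of the refinement stage
#'
#' 118 rows x 162 columns at 0.75 mm isotropic spacing, with the crop
#' centre at the continuous point `(x, y) = (80.5, 58.5)`.
#' @return list with `size`, `spacing_mm` and `center`.
#' @export
standard_grid <- function() {
  list(size = c(118L, 162L), spacing_mm = 0.75,
       center = c((162 - 1) / 2, (118 - 1) / 2))
}

#' Estimate the automated stage-2 standardization transform
#'
#' From a coarse annotation, builds the similarity transform that (i)
#' rescales each axis from the cine's pixel spacing to 0.75 mm isotropic,
#' (ii) rotates so the frame-0 valve segment is horizontal with the first
#' labelled point (anterior in 2ch, lateral in 4ch) on the left and the
#' apex side pointing down, and (iii) translates the frame-0 valve
#' midpoint onto the centre of a 118 x 162 crop.  The remaining frames'
#' midpoints determine the motion direction: the apex side is the side of
#' the frame-0 plane carrying their largest perpendicular excursion
#' (annular motion is a large one-sided swing towards the apex, so the
#' extreme-excursion side stays correct even when a coarse annotation
#' carries a systematic offset that would flip the mean offset's sign);
#' when the motion is exactly in-plane the first-point-left orientation
#' decides.
#'
#' @param coarse an `mv_annotation` with at least two annotated frames.
#' @param cine the `mv_cine` the annotation refers to (provides spacing).
#' @param target_spacing_mm standardized isotropic spacing (0.75 mm).
#' @param output_size standardized crop `c(rows, cols)` (118 x 162).
#' @return an `mv_transform` from the original grid to the standard grid.
#' @export
estimate_standardization <- function(coarse, cine,
                                     target_spacing_mm = standard_grid()$spacing_mm,
                                     output_size = standard_grid()$size) {
  n <- dim(coarse$points)[1]
  if (n < 2L)
    stopf("ambiguous apex direction: standardization needs >= 2 annotated frames")
  f0 <- annotation_frame(coarse, 0)
  p1 <- f0[1, ]; p2 <- f0[2, ]
  if (sqrt(sum((p2 - p1)^2)) < 1e-12)
    stopf("degenerate valve plane: the two frame-0 points coincide")
  sp <- cine$pixel_spacing
  sc <- sp / target_spacing_mm                       # px -> standardized px
  mid0 <- (p1 + p2) / 2
  d <- (p2 - p1) * sc                                # segment in standardized units
  theta <- -atan2(d[2], d[1])                        # rotate p1->p2 onto +x

  mids <- annotation_midpoints(coarse)
  rot <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  v <- sweep(mids[-1, , drop = FALSE], 2, mid0, "-") %*% diag(sc) %*% t(rot(theta))
  offs <- v[, 2]                                     # perpendicular offsets
  vy <- offs[which.max(abs(offs))]                   # extreme-excursion side
  if (is.finite(vy) && vy < -1e-12) theta <- theta + pi  # flip so apex maps down

  ctr <- c((output_size[2] - 1) / 2, (output_size[1] - 1) / 2)
  similarity_transform(scale = sc, rotation_deg = theta * 180 / pi,
                       translation = ctr, pivot = mid0,
                       output_size = output_size)
}

#' Apply a transform to a cine (single-pass resampling)
#'
#' Resamples every frame onto the transform's output grid in one
#' interpolation pass of the composed mapping (never sequential
#' resample-rotate-crop).  Samples falling outside the input field are
#' zero-filled.
#'
#' @param cine an `mv_cine`.
#' @param t an `mv_transform` with a non-`NULL` `output_size`.
#' @param interp interpolation kernel, default `"cubic"`.
#' @param spacing_mm pixel spacing of the output grid; inferred from the
#'   transform's scale decomposition when possible.
#' @return a list of class `mv_standardized` with elements `cine` (the
#'   resampled `mv_cine`) and `transform`.
#' @export
apply_transform <- function(cine, t, interp = "cubic", spacing_mm = NULL) {
  if (is.null(t$output_size)) stopf("transform has no output_size")
  out <- resample_frames(cine$frames, t, t$output_size, interp)
  if (is.null(spacing_mm)) {
    dc <- decompose_transform(t)
    spacing_mm <- if (!is.null(dc)) cine$pixel_spacing / dc$scale else c(NA_real_, NA_real_)
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  std <- cine_series(out, spacing_mm, cine$rr_s, cine$view, cine$meta)
  structure(list(cine = std, transform = t), class = "mv_standardized")
}

#' Serialize a transform to JSON (and back)
#'
#' The affine matrix, defining parameters and output size round-trip
#' losslessly for audit and exact replay.
#' @param t an `mv_transform`.
#' @return a JSON string.
#' @export
transform_to_json <- function(t) {
  jsonlite::toJSON(list(matrix = t$matrix,
                        output_size = t$output_size,
                        scale = t$scale, rotation_deg = t$rotation_deg,
                        translation = t$translation, pivot = t$pivot),
                   auto_unbox = TRUE, digits = I(17), null = "null")
}

#' @rdname transform_to_json
#' @param json a JSON string produced by [transform_to_json()].
#' @export
transform_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_transform(matrix(as.numeric(x$matrix), 2L, 3L),
                output_size = x$output_size, scale = x$scale,
                rotation_deg = x$rotation_deg, translation = x$translation,
                pivot = x$pivot)
}
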