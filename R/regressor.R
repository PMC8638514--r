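## Trainable landmark regressor: one grayscale image in, four coordinates
## (two MV points) out.  The backbone is a residual network built from a
## block-averaging stem followed by fully-connected residual blocks,
## trained by mini-batch Adam on the mean-square coordinate error with
## per-image median/IQR intensity normalization -- the same task,
## normalization, augmentation and optimization recipe at both pipeline
## stages.  Written in plain matrix algebra so the whole train + predict
## path is deterministic on CPU given a seed.

#' Median/IQR intensity normalization
#'
#' `(image - median) / IQR`, computed per image.  A degenerate image with
#' zero interquartile range falls back to `(image - median)` with a
#' warning.
#'
#' @param image numeric matrix.
#' @return normalized matrix of the same shape.
#' @export
normalize_intensity <- function(image) {
  med <- median(image)
  iqr <- diff(quantile(image, c(0.25, 0.75), names = FALSE))
  if (iqr == 0) {
    warnf("zero interquartile range; normalizing by median only")
    return(image - med)
  }
  (image - med) / iqr
}

#' Keypoint-consistent training augmentation
#'
#' Draws `factor` random similarity perturbations -- scale within
#' +-10%, rotation within +-10 degrees, translation within +-3 px
#' (uniform draws, about the image centre) -- and applies each
#' consistently to the image (resampled, zero-filled borders) and to the
#' target points (mapped exactly; coordinates leaving the frame are kept,
#' they remain valid regression targets).  The original pair is not
#' included in the returned list.
#'
#' @param image numeric matrix.
#' @param points 2 x 2 matrix of target points, rows = points, columns
#'   `(x, y)`.
#' @param factor number of augmented pairs to draw.
#' @param seed integer seed for the draws.
#' @param max_scale,max_rotation_deg,max_translation_px draw magnitudes.
#' @return list of `factor` elements, each `list(image, points)`.
#' @export
augment_landmarks <- function(image, points, factor = 10L, seed = 1L,
                              max_scale = 0.10, max_rotation_deg = 10,
                              max_translation_px = 3) {
  stopifnot(is.matrix(image), is.matrix(points), all(dim(points) == c(2L, 2L)))
  d <- dim(image)
  ctr <- c((d[2] - 1) / 2, (d[1] - 1) / 2)
  with_seed(seed, {
    lapply(seq_len(factor), function(k) {
      sc <- 1 + runif(1, -max_scale, max_scale)
      th <- runif(1, -max_rotation_deg, max_rotation_deg)
      tr <- runif(2, -max_translation_px, max_translation_px)
      t <- similarity_transform(scale = c(sc, sc), rotation_deg = th,
                                translation = ctr + tr, pivot = ctr,
                                output_size = d)
      img <- resample_frames(image, t, d, "cubic")[, , 1]
      list(image = img, points = map_points(points, t, "forward"))
    })
  })
}

#' Regressor configuration
#'
#' The `full` backbone is the deep configuration (many residual blocks,
#' wide hidden layers); the `tiny` backbone is the first-class
#' reduced-depth configuration used for desk-scale training and testing.
#' Training defaults follow the standard recipe: mean-square error
#' optimized by Adam, learning rate 1e-4, 20 epochs, mini-batch size 8,
#' ten-fold augmentation.
#'
#' @param backbone `"tiny"` or `"full"`.
#' @param input_size image grid `c(rows, cols)` the model consumes.
#' @param learning_rate Adam step size (> 0).
#' @param n_epochs training epochs (>= 1; fixed, no early stopping).
#' @param batch_size mini-batch size.
#' @param augmentation_factor total dataset expansion factor (>= 1): the
#'   training set holds each original once plus `factor - 1` augmented
#'   copies.
#' @param pretrained initialize the full backbone from natural-image
#'   classification weights.  No such weights ship with this package, so
#'   `TRUE` raises an error; random seeded initialization is the
#'   supported path.
#' @param seed integer seed for initialization, shuffling and
#'   augmentation.
#' @param pool block-averaging stem factor (stem output =
#'   `floor(size / pool)` grid); defaults by backbone.
#' @param hidden hidden width; defaults by backbone.
#' @param n_blocks number of residual blocks; defaults by backbone.
#' @param aug_scale,aug_rotation_deg,aug_translation_px augmentation draw
#'   magnitudes (defaults +-10%, +-10 degrees, +-3 px).  A refinement
#'   model may widen `aug_translation_px` so that its basin of attraction
#'   covers the coarse stage's residual mis-centring.
#' @return object of class `mv_regressor_config`.
#' @export
regressor_config <- function(backbone = c("tiny", "full"), input_size,
                             learning_rate = 1e-4, n_epochs = 20L,
                             batch_size = 8L, augmentation_factor = 10L,
                             pretrained = FALSE, seed = 1L,
                             pool = NULL, hidden = NULL, n_blocks = NULL,
                             aug_scale = 0.10, aug_rotation_deg = 10,
                             aug_translation_px = 3) {
  backbone <- match.arg(backbone)
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (n_epochs < 1L) stopf("n_epochs must be >= 1")
  if (augmentation_factor < 1L) stopf("augmentation_factor must be >= 1")
  defaults <- if (backbone == "tiny") list(pool = 8L, hidden = 128L, n_blocks = 2L)
              else list(pool = 4L, hidden = 512L, n_blocks = 8L)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 augmentation_factor = as.integer(augmentation_factor),
                 pretrained = isTRUE(pretrained), seed = as.integer(seed),
                 pool = as.integer(pool %||% defaults$pool),
                 hidden = as.integer(hidden %||% defaults$hidden),
                 n_blocks = as.integer(n_blocks %||% defaults$n_blocks),
                 aug_scale = aug_scale, aug_rotation_deg = aug_rotation_deg,
                 aug_translation_px = aug_translation_px),
            class = "mv_regressor_config")
}

## Block-mean pooling stem: rows and columns are averaged in pool x pool
## blocks (trailing remainder cropped), flattening the image into the
## feature vector fed to the residual blocks.
pool_image <- function(img, pool) {
  d <- dim(img)
  nr <- d[1] %/% pool; nc <- d[2] %/% pool
  m <- img[seq_len(nr * pool), seq_len(nc * pool), drop = FALSE]
  a <- colMeans(array(m, c(pool, nr * nc * pool)))     # pool rows
  m2 <- t(matrix(a, nr, nc * pool))                    # (nc*pool) x nr
  b <- colMeans(array(m2, c(pool, nc * nr)))           # pool cols
  matrix(b, nc, nr)                                    # transposed; flattened below
}

featurize <- function(images, config) {
  n <- length(images)
  f1 <- as.numeric(pool_image(normalize_intensity(images[[1]]), config$pool))
  F <- matrix(0, n, length(f1))
  F[1, ] <- f1
  if (n > 1) for (i in 2:n)
    F[i, ] <- as.numeric(pool_image(normalize_intensity(images[[i]]), config$pool))
  F
}

init_params <- function(p, config) {
  H <- config$hidden
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  params <- list(W1 = he(p, H), b1 = numeric(H))
  for (k in seq_len(config$n_blocks)) {
    params[[paste0("U", k)]] <- he(H, H)
    params[[paste0("u", k)]] <- numeric(H)
    params[[paste0("V", k)]] <- he(H, H) * 0.1   # start blocks near-identity
    params[[paste0("v", k)]] <- numeric(H)
  }
  params$Wo <- he(H, 4L) * 0.1
  params$bo <- numeric(4L)
  params
}

forward_pass <- function(F, params, config, cache = FALSE) {
  B <- config$n_blocks
  h0 <- sweep(F %*% params$W1, 2, params$b1, "+")
  a0 <- pmax(h0, 0)
  hs <- vector("list", B + 1L); zs <- vector("list", B)
  hs[[1]] <- a0
  h <- a0
  for (k in seq_len(B)) {
    zpre <- sweep(h %*% params[[paste0("U", k)]], 2, params[[paste0("u", k)]], "+")
    z <- pmax(zpre, 0)
    h <- h + sweep(z %*% params[[paste0("V", k)]], 2, params[[paste0("v", k)]], "+")
    if (cache) { zs[[k]] <- zpre; hs[[k + 1L]] <- h }
  }
  out <- sweep(h %*% params$Wo, 2, params$bo, "+")
  if (!cache) return(out)
  list(out = out, h0 = h0, hs = hs, zs = zs)
}

backward_pass <- function(F, y, params, config) {
  B <- config$n_blocks
  fw <- forward_pass(F, params, config, cache = TRUE)
  n <- nrow(F)
  r <- 2 * (fw$out - y) / (n * 4)
  g <- list(Wo = crossprod(fw$hs[[B + 1L]], r), bo = colSums(r))
  dh <- r %*% t(params$Wo)
  for (k in rev(seq_len(B))) {
    zpre <- fw$zs[[k]]
    z <- pmax(zpre, 0)
    g[[paste0("v", k)]] <- colSums(dh)
    g[[paste0("V", k)]] <- crossprod(z, dh)
    dz <- dh %*% t(params[[paste0("V", k)]])
    dzpre <- dz * (zpre > 0)
    g[[paste0("u", k)]] <- colSums(dzpre)
    g[[paste0("U", k)]] <- crossprod(fw$hs[[k]], dzpre)
    dh <- dh + dzpre %*% t(params[[paste0("U", k)]])
  }
  dh0 <- dh * (fw$h0 > 0)
  g$W1 <- crossprod(F, dh0)
  g$b1 <- colSums(dh0)
  list(grads = g, loss = mean((fw$out - y)^2))
}

#' Train the landmark regressor
#'
#' Minimizes the mean-square error between predicted and target
#' coordinate quadruples with mini-batch Adam.  The training set is the
#' originals plus `augmentation_factor - 1` keypoint-consistent augmented
#' copies of each sample, precomputed before training.  Targets are
#' handled internally on a unit grid; the recorded loss history is in
#' squared pixels of the input grid.  A fixed seed makes the whole run
#' reproducible.
#'
#' @param images list of matrices (or a rows x cols x n array), all of
#'   size `config$input_size`.
#' @param points `n x 4` matrix `(x1, y1, x2, y2)` of target coordinates
#'   in pixels (or a list of 2 x 2 point matrices).
#' @param config an [regressor_config()].
#' @return an object of class `mv_regressor` with the fitted weights,
#'   config, per-epoch training-loss history (px^2) and the
#'   normalization statistics contract.
#' @export
train_regressor <- function(images, points, config) {
  stopifnot(inherits(config, "mv_regressor_config"))
  if (config$pretrained)
    stopf("pretrained natural-image weights are not bundled; use pretrained = FALSE")
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  if (length(images) == 0L) stopf("empty training dataset")
  if (is.list(points))
    points <- do.call(rbind, lapply(points, function(p) c(t(p))))
  points <- as.matrix(points)
  if (nrow(points) != length(images))
    stopf("got %d images but %d targets", length(images), nrow(points))
  if (any(!is.finite(points))) stopf("targets must be finite")
  isz <- config$input_size
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == isz))
      stopf("image %d is %d x %d, expected %d x %d", i,
            dim(images[[i]])[1], dim(images[[i]])[2], isz[1], isz[2])
  }

  # expand with augmented copies, featurizing as we go so only feature
  # rows (not augmented images) are held in memory
  af <- config$augmentation_factor
  n0 <- length(images)
  F <- matrix(0, n0 * af, length(featurize(images[1], config)))
  pts_all <- matrix(0, n0 * af, 4L)
  F[seq_len(n0), ] <- featurize(images, config)
  pts_all[seq_len(n0), ] <- points
  if (af > 1L) {
    row <- n0
    for (i in seq_len(n0)) {
      pts <- matrix(points[i, ], 2L, 2L, byrow = TRUE)
      aug <- augment_landmarks(images[[i]], pts,
                               factor = af - 1L,
                               seed = derive_seed(config$seed, 101L, i),
                               max_scale = config$aug_scale,
                               max_rotation_deg = config$aug_rotation_deg,
                               max_translation_px = config$aug_translation_px)
      for (a in aug) {
        row <- row + 1L
        F[row, ] <- featurize(list(a$image), config)
        pts_all[row, ] <- c(t(a$points))
      }
    }
  }
  points <- pts_all
  scale4 <- c(isz[2] - 1, isz[1] - 1, isz[2] - 1, isz[1] - 1)
  y <- sweep(points, 2, scale4, "/")

  n <- nrow(F); p <- ncol(F)
  loss_hist <- numeric(config$n_epochs)
  params <- with_seed(derive_seed(config$seed, 7L), init_params(p, config))
  params$bo <- colMeans(y)   # start at the mean target (deterministic)
  mom <- lapply(params, function(x) x * 0)
  vel <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
  lr <- config$learning_rate

  with_seed(derive_seed(config$seed, 13L), {
    for (ep in seq_len(config$n_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        bp <- backward_pass(F[idx, , drop = FALSE], y[idx, , drop = FALSE],
                            params, config)
        step <- step + 1
        for (nm in names(params)) {
          gnm <- bp$grads[[nm]]
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * gnm
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * gnm^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
        ep_loss <- ep_loss + bp$loss; nb <- nb + 1
      }
      # report in squared pixels: y is on the unit grid per axis
      pred <- forward_pass(F, params, config)
      dpx <- sweep(pred - y, 2, scale4, "*")
      loss_hist[ep] <- mean(dpx^2)
    }
  })

  structure(list(config = config, params = params,
                 input_size = isz, target_scale = scale4,
                 normalization = list(method = "per_image_median_iqr"),
                 loss_history = loss_hist),
            class = "mv_regressor")
}

#' @export
print.mv_regressor <- function(x, ...) {
  cat(sprintf("<mv_regressor> %s backbone, input %d x %d, final loss %.4g px^2\n",
              x$config$backbone, x$input_size[1], x$input_size[2],
              tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict MV points on one image or an image stack
#'
#' Applies the model's stored intensity normalization, runs the network
#' and returns coordinates in the input image's own pixel frame.
#'
#' @param model an `mv_regressor` (or an [oracle_regressor()]).
#' @param image matrix of the model's input size, or a rows x cols x n
#'   stack.
#' @param ... further arguments for methods (the oracle uses `frame` and
#'   `transform`).
#' @return `n x 4` matrix of `(x1, y1, x2, y2)` per frame (one row for a
#'   single image).
#' @export
predict_points <- function(model, image, ...) UseMethod("predict_points")

#' @export
predict_points.mv_regressor <- function(model, image, ...) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (!all(d[1:2] == model$input_size))
    stopf("image is %d x %d but the model expects %d x %d",
          d[1], d[2], model$input_size[1], model$input_size[2])
  imgs <- lapply(seq_len(d[3]), function(i) image[, , i])
  F <- featurize(imgs, model$config)
  out <- forward_pass(F, model$params, model$config)
  out <- sweep(out, 2, model$target_scale, "*")
  colnames(out) <- c("x1", "y1", "x2", "y2")
  out
}

#' Ground-truth lookup stand-in for a regressor
#'
#' Satisfies the [predict_points()] contract by returning the stored
#' ground-truth points of the requested frame, mapped through the
#' transform the pipeline used to build the image it is shown.  Used to
#' isolate pipeline plumbing (resize, standardization, inverse mapping,
#' iteration) from learning.
#'
#' @param annotation the ground-truth `mv_annotation` in original image
#'   coordinates.
#' @return object of class `mv_oracle`.
#' @export
oracle_regressor <- function(annotation) {
  structure(list(annotation = annotation), class = "mv_oracle")
}

#' @rdname oracle_regressor
#' @param model,image,frame,transform,... see [predict_points()]; `frame`
#'   is the 0-based frame index, `transform` the grid transform (or
#'   `NULL` for the original grid).
#' @export
predict_points.mv_oracle <- function(model, image, frame = 0L,
                                     transform = NULL, ...) {
  pts <- annotation_frame(model$annotation, frame)
  if (!is.null(transform)) pts <- map_points(pts, transform, "forward")
  matrix(c(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2]), 1L, 4L,
         dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
}

#' Save / load a trained regressor
#'
#' The weights are written in R's native serialized format with a JSON
#' sidecar (`<path>.json`) carrying the config and normalization
#' statistics for audit.
#' @param model an `mv_regressor`.
#' @param path file path (conventionally `.rds`).
#' @return `save_regressor` the path, invisibly; `load_regressor` the
#'   model.
#' @export
save_regressor <- function(model, path) {
  write_atomic(path, function(p) saveRDS(model, p))
  sidecar <- list(config = unclass(model$config),
                  normalization = model$normalization,
                  input_size = model$input_size,
                  final_loss_px2 = tail(model$loss_history, 1))
  write_atomic(paste0(path, ".json"), function(p)
    jsonlite::write_json(sidecar, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  invisible(path)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  readRDS(path)
}
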