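## Training-set assembly and the canonical desk-scale configurations.

## Fetch one subject/view's cine + ground-truth annotation, whether the
## manifest carries in-memory data (write_images = FALSE) or file paths.
fetch_cine_view <- function(manifest, subj, view, dir = NULL) {
  entry <- subj$views[[view]]
  if (!is.null(entry$data)) return(entry$data)
  if (is.null(dir)) stopf("manifest has no in-memory data; supply the dataset dir")
  cine <- read_cine(file.path(dir, entry$cine_path), view = view)
  anns <- read_annotations(file.path(dir, subj$annotation_path))
  ann <- if (inherits(anns, "mv_annotation")) anns
         else anns[[paste(subj$subject_id, view, "ground_truth", sep = "|")]]
  list(cine = cine, annotation = ann)
}

## Evenly spaced frame subset of at most max_frames (0-based indices).
frame_subset <- function(n, max_frames) {
  if (!is.finite(max_frames) || n <= max_frames) return(seq_len(n))
  unique(round(seq(1, n, length.out = max_frames)))
}

#' Assemble a stage training set from a dataset
#'
#' For stage 1, every selected frame is resized to the coarse 160 x 160
#' grid and the ground-truth points are mapped along.  For stage 2, the
#' standardization is estimated from the ground-truth annotation
#' (training-time teacher forcing; the training augmentation is what
#' teaches the refinement model to tolerate the coarse stage's residual
#' misalignment at inference time), the cine is standardized and the
#' points mapped onto the standard grid.
#'
#' @param manifest a manifest from [make_dataset()] (in-memory or read
#'   back via [read_manifest()]).
#' @param stage 1 (coarse grid) or 2 (standard grid).
#' @param view `"2ch"` or `"4ch"`.
#' @param dir dataset directory when the manifest references files.
#' @param split which split to use, `"train"` (default) or `"test"`.
#' @param max_frames_per_cine cap on frames taken per cine (evenly
#'   spaced); temporally adjacent frames are near-duplicates, so a
#'   moderate cap loses little diversity.
#' @return list with `images` (list of matrices) and `targets`
#'   (`n x 4` matrix).
#' @export
training_set <- function(manifest, stage, view, dir = NULL, split = "train",
                         max_frames_per_cine = Inf) {
  images <- list(); targets <- list()
  for (subj in manifest$subjects) {
    if (subj$split != split) next
    d <- fetch_cine_view(manifest, subj, view, dir)
    keep <- frame_subset(n_frames(d$cine), max_frames_per_cine)
    sub <- cine_series(d$cine$frames[, , keep, drop = FALSE],
                       d$cine$pixel_spacing, d$cine$rr_s, d$cine$view)
    if (stage == 1L) {
      rs <- resize_to_network_grid(sub)
      frames <- rs$cine$frames
      mapped <- map_annotation(d$annotation, rs$transform, "forward")
    } else {
      t <- estimate_standardization(d$annotation, d$cine)
      std <- apply_transform(sub, t)
      frames <- std$cine$frames
      mapped <- map_annotation(d$annotation, t, "forward")
    }
    mm <- annotation_matrix(mapped)[keep, , drop = FALSE]
    for (i in seq_along(keep)) {
      images[[length(images) + 1L]] <- frames[, , i]
      targets[[length(targets) + 1L]] <- mm[i, ]
    }
  }
  if (length(images) == 0L)
    stopf("no %s subjects with view %s in the manifest", split, view)
  list(images = images, targets = do.call(rbind, targets))
}

#' Canonical desk-scale stage configurations
#'
#' The tiny-backbone training configurations used by the package's own
#' benchmarks: the coarse model sees the full appearance variability
#' (arbitrary orientation, scale, field of view), so it gets the finer
#' stem and wider hidden layer; the refinement model works on
#' standardized crops, so a lighter network suffices but its translation
#' and rotation augmentation is widened so its basin of attraction covers
#' the coarse stage's residual mis-centring.
#'
#' @param seed integer seed; the two models derive distinct child seeds.
#' @return list with elements `stage1` and `stage2`
#'   ([regressor_config()] objects).
#' @export
default_stage_configs <- function(seed = 1L) {
  list(stage1 = regressor_config("tiny", c(160L, 160L),
                                 learning_rate = 1e-3, n_epochs = 28L,
                                 batch_size = 32L, augmentation_factor = 3L,
                                 pool = 5L, hidden = 192L,
                                 seed = derive_seed(seed, 1L)),
       stage2 = regressor_config("tiny", standard_grid()$size,
                                 learning_rate = 1e-3, n_epochs = 20L,
                                 batch_size = 32L, augmentation_factor = 3L,
                                 aug_translation_px = 16, aug_rotation_deg = 15,
                                 seed = derive_seed(seed, 2L)))
}

#' Train both stage models for one view
#'
#' @param manifest dataset manifest.
#' @param view `"2ch"` or `"4ch"`.
#' @param dir dataset directory for file-backed manifests.
#' @param configs list with `stage1`/`stage2` configs, defaults to
#'   [default_stage_configs()].
#' @param max_frames_per_cine training frame cap per cine.
#' @return list with trained `stage1` and `stage2` models.
#' @export
train_view_models <- function(manifest, view, dir = NULL,
                              configs = default_stage_configs(),
                              max_frames_per_cine = 12L) {
  ts1 <- training_set(manifest, 1L, view, dir, max_frames_per_cine = max_frames_per_cine)
  ts2 <- training_set(manifest, 2L, view, dir, max_frames_per_cine = max_frames_per_cine)
  list(stage1 = train_regressor(ts1$images, ts1$targets, configs$stage1),
       stage2 = train_regressor(ts2$images, ts2$targets, configs$stage2))
}
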