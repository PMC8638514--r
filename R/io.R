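## Readers/writers: NIfTI cines, PNG-directory cines with a JSON
## metadata sidecar, and the annotation CSV schema.  Coordinates are
## always stored in original-image pixels with the spacing carried
## separately, so no value is ever converted twice.

VALID_LABELS <- c("anterior", "inferior", "lateral", "septal", "p1", "p2")
VALID_SOURCES <- c("manual", "stage1", "stage1+2", "stage1+2+2", "ground_truth")

#' Write a cine as a multi-frame NIfTI file
#'
#' Frames are stored along the last axis; the row/column spacings go into
#' the spatial pixdim slots and the inter-frame interval (RR divided by
#' `n_frames - 1`) into the third.
#' @param cine an `mv_cine`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype on-disk NIfTI datatype; the default single-precision
#'   float keeps dataset directories compact.
#' @return the path, invisibly.
#' @export
write_cine <- function(cine, path, datatype = "float") {
  n <- n_frames(cine)
  dt <- if (n > 1) cine$rr_s / (n - 1) else cine$rr_s
  img <- RNifti::asNifti(cine$frames)
  RNifti::pixdim(img) <- c(cine$pixel_spacing[2], cine$pixel_spacing[1], dt)
  write_atomic(path, function(p) {
    # writeNifti derives the on-disk name from the extension of its target
    tmp2 <- paste0(p, if (grepl("\\.gz$", path)) ".nii.gz" else ".nii")
    RNifti::writeNifti(img, tmp2, datatype = datatype)
    file.rename(tmp2, p)
  })
  invisible(path)
}

#' Read a cine series
#'
#' Supported containers: a multi-frame NIfTI file (frames along the last
#' axis) or a directory of ordered PNG frames with a `meta.json` sidecar
#' (`pixel_spacing_mm`, `rr_s`, optional `view`).  Missing spacing or
#' timing metadata falls back to documented defaults (1.0 mm, RR 1.0 s)
#' with warnings.  DICOM input is not supported.
#'
#' @param path NIfTI file or PNG directory.
#' @param view optional view label to attach.
#' @return an `mv_cine`.
#' @export
read_cine <- function(path, view = NULL) {
  if (dir.exists(path)) return(read_cine_png_dir(path, view))
  if (!file.exists(path)) stopf("cannot read cine: no such file: %s", path)
  if (grepl("\\.dcm$", path, ignore.case = TRUE))
    stopf("DICOM input is not supported; convert to NIfTI or PNG+sidecar")
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("unsupported cine container: %s", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (length(dim(a)) != 3L) stopf("expected a 2D multi-frame NIfTI: %s", path)
  pd <- RNifti::pixdim(img)
  spacing <- c(pd[2], pd[1])
  n <- dim(a)[3]
  rr <- if (length(pd) >= 3L && n > 1L) pd[3] * (n - 1) else {
    warnf("no frame timing in %s; assuming RR 1.0 s", path); 1.0
  }
  cine_series(a, spacing, rr, view = view)
}

read_cine_png_dir <- function(path, view = NULL) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (any(grepl("\\.dcm$", list.files(path), ignore.case = TRUE)))
    stopf("DICOM input is not supported; convert to NIfTI or PNG+sidecar")
  if (length(files) == 0L) stopf("no PNG frames found in %s", path)
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  d1 <- dim(frames[[1]])
  for (i in seq_along(frames))
    if (!all(dim(frames[[i]]) == d1))
      stopf("inconsistent frame sizes in %s (frame %d is %d x %d, first is %d x %d)",
            path, i - 1L, dim(frames[[i]])[1], dim(frames[[i]])[2], d1[1], d1[2])
  arr <- array(unlist(frames), c(d1, length(frames)))
  meta_path <- file.path(path, "meta.json")
  spacing <- NULL; rr <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    spacing <- meta$pixel_spacing_mm
    rr <- meta$rr_s
    if (is.null(view)) view <- meta$view
  }
  if (is.null(spacing)) {
    warnf("no pixel spacing metadata in %s; assuming 1.0 mm", path)
    spacing <- c(1, 1)
  }
  if (is.null(rr)) {
    warnf("no frame timing metadata in %s; assuming RR 1.0 s", path)
    rr <- 1.0
  }
  cine_series(arr, spacing, rr, view = view)
}

#' Debug dump of a cine as one PNG per frame plus sidecar
#' @param cine an `mv_cine`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_cine_png <- function(cine, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- cine$frames
  f <- (f - min(f)) / max(max(f) - min(f), .Machine$double.eps)
  for (i in seq_len(dim(f)[3]))
    png::writePNG(f[, , i], file.path(dir, sprintf("frame-%03d.png", i - 1L)))
  write_atomic(file.path(dir, "meta.json"), function(p)
    jsonlite::write_json(list(pixel_spacing_mm = cine$pixel_spacing,
                              rr_s = cine$rr_s, view = cine$view),
                         p, auto_unbox = TRUE, digits = NA))
  invisible(dir)
}

#' Annotation as a data frame in the CSV schema
#'
#' Long format: one row per (frame, point) with columns `subject_id`,
#' `view`, `frame_index` (0-based), `point_label`, `x_px`, `y_px`,
#' `source`.
#' @param ann an `mv_annotation`.
#' @param subject_id subject identifier.
#' @param source provenance label (`manual`, `stage1`, `stage1+2`,
#'   `stage1+2+2` or `ground_truth`).
#' @return data.frame.
#' @export
annotation_table <- function(ann, subject_id = "unknown", source = "manual") {
  source <- match.arg(source, VALID_SOURCES)
  n <- dim(ann$points)[1]
  data.frame(subject_id = subject_id,
             view = ann$view %||% "2ch",
             frame_index = rep(0:(n - 1), each = 2L),
             point_label = rep(ann$labels, n),
             x_px = as.numeric(t(ann$points[, , 1])),
             y_px = as.numeric(t(ann$points[, , 2])),
             source = source)
}

#' Write annotations to CSV
#' @param ann an `mv_annotation` or a data.frame already in the schema.
#' @param path output CSV path.
#' @param subject_id,source passed to [annotation_table()].
#' @return the path, invisibly.
#' @export
write_annotations <- function(ann, path, subject_id = "unknown",
                              source = "manual") {
  df <- if (is.data.frame(ann)) ann
        else annotation_table(ann, subject_id, source)
  write_atomic(path, function(p) write.csv(df, p, row.names = FALSE))
  invisible(path)
}

#' Read annotations from CSV
#'
#' Validates the schema (known labels, no duplicate (frame, label) rows,
#' exactly two labels per frame) and partitions the rows by
#' (subject, view, source).
#'
#' @param path CSV path in the [annotation_table()] schema.
#' @return a single `mv_annotation` when the file holds one
#'   (subject, view, source) group, otherwise a named list of them
#'   (names `subject|view|source`).  Each annotation carries `subject_id`
#'   and `source` attributes.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "view", "frame_index", "point_label", "x_px", "y_px", "source")
  if (!all(need %in% names(df)))
    stopf("annotation file %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  bad <- setdiff(unique(df$point_label), VALID_LABELS)
  if (length(bad)) stopf("unknown point label(s): %s", paste(bad, collapse = ", "))

  key <- paste(df$subject_id, df$view, df$source, sep = "|")
  groups <- split(df, key)
  out <- lapply(groups, function(g) {
    dup <- duplicated(g[, c("frame_index", "point_label")])
    if (any(dup)) stopf("duplicate (frame, label) rows in %s", path)
    per_frame <- table(g$frame_index)
    if (any(per_frame != 2L))
      stopf("each frame needs exactly two labelled points (frame %s has %d)",
            names(per_frame)[per_frame != 2L][1], per_frame[per_frame != 2L][1])
    if (length(unique(g$point_label)) != 2L)
      stopf("each frame needs exactly two consistently labelled points; got labels %s",
            paste(sort(unique(g$point_label)), collapse = ", "))
    view <- g$view[1]
    labels <- if (view %in% c("2ch", "4ch")) {
      conv <- view_labels(view)
      if (all(conv %in% g$point_label)) conv else sort(unique(g$point_label))
    } else sort(unique(g$point_label))
    frames <- sort(unique(g$frame_index))
    pts <- array(NA_real_, c(length(frames), 2L, 2L))
    for (j in 1:2) {
      gj <- g[g$point_label == labels[j], ]
      gj <- gj[order(gj$frame_index), ]
      pts[, j, 1] <- gj$x_px
      pts[, j, 2] <- gj$y_px
    }
    ann <- mv_annotation(pts, labels = labels,
                         view = if (view %in% c("2ch", "4ch")) view else NULL)
    attr(ann, "subject_id") <- g$subject_id[1]
    attr(ann, "source") <- g$source[1]
    ann
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Read a dataset manifest written by [make_dataset()]
#' @param dir dataset directory.
#' @return the manifest list.
#' @export
read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (!file.exists(p)) stopf("no manifest.json in %s", dir)
  jsonlite::fromJSON(p, simplifyVector = FALSE)
}
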