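## Synthetic long-axis cine phantom: a stylized left ventricle (bright
## blood pool inside a dark myocardial shell inside a bright fat band)
## whose basal plane translates rigidly along the long axis following a
## prescribed motion profile.  Ground-truth MV point trajectories are
## computed analytically, never read back from pixels.  The appearance is
## deliberately schematic: the goal is detectability, not realism.

#' Rendering parameters for the synthetic cine phantom
#'
#' @param pixel_spacing_mm in-plane spacing, mm, `c(x, y)` or scalar;
#'   must lie in [0.5, 3.0].
#' @param image_size image grid `c(rows, cols)`.
#' @param heart_rotation_deg global in-plane orientation of the long
#'   axis; unrestricted (wraps mod 360).  At 0 the valve segment is
#'   horizontal with the first point on the left and the apex down.
#' @param heart_center_px valve-centre position `c(x, y)` in pixels at
#'   end-diastole; defaults to slightly above the image centre.
#' @param annulus_width_mm distance between the two MV points.
#' @param view `"2ch"` or `"4ch"` (fixes the point labels).
#' @param annotation_convention `"valve_intersection"` places the ground
#'   truth at the analytic annulus endpoints; `"basal_myocardium"`
#'   offsets both points along the wall direction towards the apex by
#'   `convention_offset_mm` (the two manual-annotation principles).
#' @param convention_offset_mm along-wall offset under the
#'   `basal_myocardium` convention.
#' @return an object of class `mv_render_params`.
#' @export
render_params <- function(pixel_spacing_mm = 1.5, image_size = c(192L, 192L),
                          heart_rotation_deg = 0, heart_center_px = NULL,
                          annulus_width_mm = 30, view = "2ch",
                          annotation_convention = c("valve_intersection",
                                                    "basal_myocardium"),
                          convention_offset_mm = 2) {
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm < 0.5) || any(pixel_spacing_mm > 3.0))
    stopf("pixel_spacing_mm must lie in [0.5, 3.0]")
  image_size <- as.integer(image_size)
  if (any(image_size < 16L)) stopf("image_size too small")
  if (annulus_width_mm <= 0) stopf("annulus_width_mm must be positive")
  view <- match.arg(view, c("2ch", "4ch"))
  annotation_convention <- match.arg(annotation_convention)
  if (is.null(heart_center_px))
    heart_center_px <- c((image_size[2] - 1) / 2, (image_size[1] - 1) / 2 - 8)
  structure(list(pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 image_size = image_size,
                 heart_rotation_deg = heart_rotation_deg %% 360,
                 heart_center_px = as.numeric(heart_center_px),
                 annulus_width_mm = annulus_width_mm, view = view,
                 annotation_convention = annotation_convention,
                 convention_offset_mm = convention_offset_mm),
            class = "mv_render_params")
}

# Fixed anatomy of the phantom (mm).
PHANTOM <- list(lv_length = 75, wall_mm = 10, fat_rel = 1.25,
                atrium_depth = 35,
                bg = 0.15, fat = 0.9, myo = 0.25, blood = 0.85, atrium = 0.55)

#' Render a synthetic cine with analytic ground truth
#'
#' @param motion an [motion_profile_params()] object.
#' @param render an [render_params()] object.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with elements `cine` (an `mv_cine`) and `annotation`
#'   (the exact continuous MV point trajectory as an `mv_annotation`).
#' @export
render_cine <- function(motion, render, seed = 1L) {
  stopifnot(inherits(motion, "mv_motion_params"),
            inherits(render, "mv_render_params"))
  n <- motion$n_frames
  nr <- render$image_size[1]; nc <- render$image_size[2]
  sp <- render$pixel_spacing_mm
  disp <- generate_displacement_profile(motion)

  th <- render$heart_rotation_deg * pi / 180
  eb <- c(cos(th), sin(th))          # annulus direction (p1 -> p2)
  ea <- c(-sin(th), cos(th))         # long-axis direction, towards apex

  rb <- render$annulus_width_mm / 2
  # ground-truth trajectories (px), rigid translation of the base plane
  off <- if (render$annotation_convention == "basal_myocardium")
    render$convention_offset_mm else 0
  pts <- array(NA_real_, c(n, 2L, 2L))
  for (i in seq_len(n)) {
    s <- disp$values[i]
    for (j in 1:2) {
      v_mm <- (if (j == 1) -rb else rb) * eb + (s + off) * ea
      p <- render$heart_center_px + v_mm / sp
      if (p[1] < 0 || p[1] > nc - 1 || p[2] < 0 || p[2] > nr - 1)
        stopf("MV point %d outside the image at frame %d", j, i - 1L)
      pts[i, j, ] <- p
    }
  }

  # pixel grid in heart coordinates (mm): b across the annulus, a towards apex
  xs <- (0:(nc - 1) - render$heart_center_px[1]) * sp[1]
  ys <- (0:(nr - 1) - render$heart_center_px[2]) * sp[2]
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  B <- X * eb[1] + Y * eb[2]
  A <- X * ea[1] + Y * ea[2]

  L <- PHANTOM$lv_length; w <- PHANTOM$wall_mm
  sig <- function(z) 1 / (1 + exp(-z))
  eps_in <- 1.5 / rb; eps_out <- 1.5 / (rb + w); eps_a <- 1.2

  frames <- array(0, c(nr, nc, n))
  with_seed(derive_seed(seed, 811L), {
    for (i in seq_len(n)) {
      A1 <- A - disp$values[i]
      pos <- pmax(A1, 0)
      rin <- sqrt((B / rb)^2 + (pos / L)^2)
      # above the base the cavity/wall continue as straight atrial walls
      rin[A1 < 0] <- abs(B[A1 < 0]) / rb
      rout <- sqrt((B / (rb + w))^2 + (pos / (L + w))^2)
      rout[A1 < 0] <- abs(B[A1 < 0]) / (rb + w)
      m_fat <- sig((PHANTOM$fat_rel - rout) / eps_out)
      m_out <- sig((1 - rout) / eps_out)
      m_in <- sig((1 - rin) / eps_in)
      m_vent <- sig(A1 / eps_a)
      m_atr_end <- sig((A1 + PHANTOM$atrium_depth) / eps_a)
      blood <- PHANTOM$blood * m_vent +
        (PHANTOM$atrium * m_atr_end + PHANTOM$bg * (1 - m_atr_end)) * (1 - m_vent)
      img <- PHANTOM$bg * (1 - m_fat) + PHANTOM$fat * m_fat
      img <- img * (1 - m_out) + PHANTOM$myo * m_out
      img <- img * (1 - m_in) + blood * m_in
      if (motion$noise_sd > 0)
        img <- img + rnorm(length(img), sd = motion$noise_sd)
      frames[, , i] <- img
    }
  })

  cine <- cine_series(frames, sp, rr_s = 60 / motion$hr_bpm, view = render$view,
                      meta = list(seed = seed))
  ann <- mv_annotation(pts, view = render$view)
  list(cine = cine, annotation = ann)
}

#' Default per-subject sampling ranges for synthetic datasets
#'
#' Each entry is `c(min, max)`; values are drawn uniformly per subject.
#' The imaging ranges mirror routine long-axis cine acquisitions
#' (spacing 1.3-1.7 mm, 25-50 frames per cycle, arbitrary in-plane
#' orientation and field-of-view placement); the motion ranges span
#' reduced to supra-normal longitudinal function.
#' @return named list of ranges.
#' @export
default_param_ranges <- function() {
  list(mapse_mm = c(8, 18), hr_bpm = c(50, 90), n_frames = c(25, 50),
       systole_fraction = c(0.32, 0.40), diastasis_fraction = c(0.24, 0.32),
       atrial_kick_fraction_of_mapse = c(0.18, 0.30), noise_sd = c(0.02, 0.05),
       pixel_spacing_mm = c(1.3, 1.7), image_size = c(144, 208),
       heart_rotation_deg = c(0, 360), annulus_width_mm = c(26, 34),
       center_jitter_mm = c(-8, 8))
}

draw_range <- function(rg, integer = FALSE) {
  v <- runif(1, rg[1], rg[2])
  if (integer) as.integer(round(v)) else v
}

## Sample one subject's motion + per-view render parameters.
sample_subject_params <- function(ranges, convention = "valve_intersection",
                                  convention_offset_mm = 2) {
  motion <- motion_profile_params(
    mapse_mm = draw_range(ranges$mapse_mm),
    hr_bpm = draw_range(ranges$hr_bpm),
    n_frames = draw_range(ranges$n_frames, integer = TRUE),
    systole_fraction = draw_range(ranges$systole_fraction),
    diastasis_fraction = draw_range(ranges$diastasis_fraction),
    atrial_kick_fraction_of_mapse = draw_range(ranges$atrial_kick_fraction_of_mapse),
    noise_sd = draw_range(ranges$noise_sd))
  views <- lapply(c("2ch", "4ch"), function(v) {
    size <- c(draw_range(ranges$image_size, integer = TRUE),
              draw_range(ranges$image_size, integer = TRUE))
    spacing <- draw_range(ranges$pixel_spacing_mm)
    jit <- c(draw_range(ranges$center_jitter_mm), draw_range(ranges$center_jitter_mm))
    render_params(pixel_spacing_mm = spacing, image_size = size,
                  heart_rotation_deg = draw_range(ranges$heart_rotation_deg),
                  heart_center_px = c((size[2] - 1) / 2, (size[1] - 1) / 2) + jit / spacing,
                  annulus_width_mm = draw_range(ranges$annulus_width_mm),
                  view = v, annotation_convention = convention,
                  convention_offset_mm = convention_offset_mm)
  })
  names(views) <- c("2ch", "4ch")
  list(motion = motion, views = views)
}

#' Generate a synthetic cine dataset with manifest
#'
#' Samples per-subject motion and rendering parameters uniformly from
#' `param_ranges`, renders both chamber views per subject, writes NIfTI
#' cines, ground-truth annotation CSVs and a JSON manifest.  The
#' train/test split is disjoint by subject, never by frame.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param dir output directory.
#' @param param_ranges named list of `c(min, max)` ranges, see
#'   [default_param_ranges()]; collapse a range to a point to fix it.
#' @param split named fractions `c(train = , test = )`; must sum to <= 1.
#' @param seed integer seed driving all randomness.
#' @param convention,convention_offset_mm annotation convention applied
#'   to the whole dataset.
#' @param write_images set `FALSE` to keep cines in memory only (the
#'   manifest then carries no image paths); used for fast in-memory runs.
#' @return the manifest as a list, invisibly when written to disk.  With
#'   `write_images = FALSE` the rendered objects are returned in
#'   `$subjects[[i]]$data`.
#' @export
make_dataset <- function(n_subjects, dir = NULL,
                         param_ranges = default_param_ranges(),
                         split = c(train = 0.8, test = 0.2), seed = 1L,
                         convention = "valve_intersection",
                         convention_offset_mm = 2,
                         write_images = !is.null(dir)) {
  if (n_subjects < 2L) stopf("n_subjects must be >= 2")
  if (sum(split) > 1 + 1e-9) stopf("split fractions sum to more than 1")
  ranges <- utils::modifyList(default_param_ranges(), param_ranges)
  n_train <- round(n_subjects * split[["train"]])
  ids <- sprintf("sub-%03d", seq_len(n_subjects))
  splits <- rep("test", n_subjects)
  splits[seq_len(n_train)] <- "train"

  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    pars <- with_seed(derive_seed(seed, 17L, s),
                      sample_subject_params(ranges, convention, convention_offset_mm))
    views <- list()
    ann_rows <- list()
    for (v in c("2ch", "4ch")) {
      rs <- derive_seed(seed, 29L, s, if (v == "2ch") 1L else 2L)
      out <- render_cine(pars$motion, pars$views[[v]], seed = rs)
      entry <- list(view = v, seed = rs,
                    pixel_spacing_mm = pars$views[[v]]$pixel_spacing_mm,
                    rr_s = out$cine$rr_s)
      if (write_images) {
        img_path <- file.path(dir, "images", sprintf("%s_%s.nii", ids[s], v))
        write_cine(out$cine, img_path)
        entry$cine_path <- file.path("images", basename(img_path))
        ann_rows[[v]] <- annotation_table(out$annotation, subject_id = ids[s],
                                          source = "ground_truth")
      } else {
        entry$data <- out
      }
      views[[v]] <- entry
    }
    subj <- list(subject_id = ids[s], split = splits[s], views = views,
                 params = list(motion = unclass(pars$motion),
                               render = lapply(pars$views, unclass)))
    if (write_images) {
      subj$annotation_path <- file.path("annotations", paste0(ids[s], ".csv"))
      write_atomic(file.path(dir, subj$annotation_path), function(p)
        write.csv(do.call(rbind, ann_rows), p, row.names = FALSE))
    }
    subjects[[s]] <- subj
  }

  manifest <- list(n_subjects = n_subjects, seed = as.integer(seed),
                   split = as.list(split), convention = convention,
                   convention_offset_mm = convention_offset_mm,
                   subjects = subjects)
  if (write_images) {
    write_atomic(file.path(dir, "manifest.json"), function(p)
      jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE))
    return(invisible(manifest))
  }
  manifest
}
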