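## End-to-end synthetic benchmark: simulate a cohort, train the
## dual-stage models, track the held-out subjects and summarize spatial
## and clinical agreement -- the package's scaled-down analogue of a
## train/test study on clinical data.

#' Run the end-to-end synthetic tracking study
#'
#' Simulates `n_subjects` two-view cine phantoms (written to `dir` as
#' NIfTI + CSV), trains tiny-backbone stage-1 and stage-2 regressors per
#' view on the training split, tracks every test subject with the full
#' dual-stage pipeline (`stage 1+2+2`), and computes the stage-wise
#' spatial agreement plus subject-level clinical agreement (MAPSE and
#' e' ICC against ground truth, from the resultant two-view displacement
#' curves).
#'
#' @param n_subjects cohort size (default 240, split 5/6 train, 1/6 test).
#' @param seed integer seed driving simulation and training.
#' @param dir dataset directory; defaults to a fresh temporary directory.
#' @param split train/test fractions.
#' @param configs stage configurations, defaults to
#'   [default_stage_configs()] seeded from `seed`.
#' @param max_frames_per_cine training frame cap per cine.
#' @param n_refine refinement passes for tracking.
#' @param quiet suppress progress messages.
#' @param cleanup delete the dataset directory on exit (default when it
#'   was auto-created under the session temporary directory).
#' @return list with `report` (the [stagewise_report()] data.frame),
#'   `clinical` (per-subject data.frame of predicted and ground-truth
#'   MAPSE/s'/e'/a'), `mapse_icc`, `e_prime_icc`, `disp_abs_mean_mm`
#'   (mean absolute per-frame displacement error at the final stage),
#'   `models`, and `n_test`.
#' @export
benchmark_pipeline <- function(n_subjects = 240L, seed = 1L, dir = NULL,
                               split = c(train = 5 / 6, test = 1 / 6),
                               configs = default_stage_configs(seed),
                               max_frames_per_cine = 12L, n_refine = 2L,
                               quiet = FALSE, cleanup = is.null(dir)) {
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(dir)) dir <- file.path(tempdir(), sprintf("mvtrack-bench-%d", seed))
  if (cleanup) on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  ds <- make_dataset(n_subjects, dir = dir, seed = derive_seed(seed, 5L),
                     split = split)
  say("simulated %d subjects (%s)", n_subjects, dir)

  models <- list()
  for (v in c("2ch", "4ch")) {
    models[[v]] <- train_view_models(ds, v, dir = dir, configs = configs,
                                     max_frames_per_cine = max_frames_per_cine)
    say("trained %s models (final losses %.2f / %.2f px^2)", v,
        tail(models[[v]]$stage1$loss_history, 1),
        tail(models[[v]]$stage2$loss_history, 1))
  }

  results <- list(); gts <- list(); spacings <- list(); rrs <- c()
  clin <- list()
  for (s in ds$subjects) {
    if (s$split != "test") next
    trk <- list(); dat <- list()
    for (v in c("2ch", "4ch")) {
      d <- fetch_cine_view(ds, s, v, dir)
      dat[[v]] <- d
      tr <- track_mv(d$cine, models[[v]]$stage1, models[[v]]$stage2,
                     n_refine = n_refine)
      trk[[v]] <- tr
      results[[length(results) + 1L]] <- tr
      gts[[length(gts) + 1L]] <- d$annotation
      spacings[[length(spacings) + 1L]] <- d$cine$pixel_spacing
      rrs <- c(rrs, d$cine$rr_s)
    }
    final <- tail(names(trk[["2ch"]]$stages), 1)
    sp2 <- dat[["2ch"]]$cine$pixel_spacing
    sp4 <- dat[["4ch"]]$cine$pixel_spacing
    rr <- dat[["2ch"]]$cine$rr_s
    mp <- subject_metrics(trk[["2ch"]]$stages[[final]], trk[["4ch"]]$stages[[final]],
                          sp2, sp4, rr)
    mg <- subject_metrics(dat[["2ch"]]$annotation, dat[["4ch"]]$annotation,
                          sp2, sp4, rr)
    clin[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id,
      mapse_pred = mp$mapse_mm, mapse_gt = mg$mapse_mm,
      s_prime_pred = mp$s_prime_cm_s, s_prime_gt = mg$s_prime_cm_s,
      e_prime_pred = mp$e_prime_cm_s, e_prime_gt = mg$e_prime_cm_s,
      a_prime_pred = mp$a_prime_cm_s, a_prime_gt = mg$a_prime_cm_s)
  }
  say("tracked %d held-out subjects", length(clin))

  report <- stagewise_report(results, gts, spacings, rrs)
  clinical <- do.call(rbind, clin)
  final_stage <- report$stage[nrow(report)]
  disp_abs <- local({
    tot <- 0; n <- 0
    for (i in seq_along(results)) {
      dp <- plane_displacement(results[[i]]$stages[[final_stage]], spacings[[i]],
                               rr_s = rrs[i])
      dg <- plane_displacement(gts[[i]], spacings[[i]], rr_s = rrs[i])
      e <- displacement_error(dp, dg)
      tot <- tot + sum(abs(e)); n <- n + length(e)
    }
    tot / n
  })
  list(report = report, clinical = clinical,
       mapse_icc = icc_agreement(clinical$mapse_gt, clinical$mapse_pred)$icc,
       e_prime_icc = icc_agreement(clinical$e_prime_gt, clinical$e_prime_pred)$icc,
       disp_abs_mean_mm = disp_abs,
       models = models, n_test = length(clin))
}

#' Cross-convention generalization probe
#'
#' Trains a refinement (stage-2) model on cines annotated under the
#' valve-intersection convention, then evaluates its predictions against
#' ground truth placed under the basal-myocardium convention (both points
#' offset `offset_mm` along the wall towards the apex) on held-out cines
#' of the same geometry.  The Euclidean error absorbs the full systematic
#' offset while the plane-displacement error stays small, because each
#' curve is measured against its own end-diastolic reference plane.
#'
#' @param n_subjects cohort size for the probe.
#' @param seed integer seed.
#' @param offset_mm the convention offset between the two annotation
#'   principles.
#' @param view chamber view used for the probe.
#' @param configs stage configs (only `stage2` is used).
#' @return list with `euclid_mean_mm`, `disp_err_abs_mean_mm`,
#'   `within_convention_euclid_mm` (same model against its own
#'   convention), and `n_test`.
#' @export
cross_convention_probe <- function(n_subjects = 60L, seed = 1L, offset_mm = 2,
                                   view = "2ch",
                                   configs = default_stage_configs(seed)) {
  ds <- make_dataset(n_subjects, seed = derive_seed(seed, 23L),
                     split = c(train = 5 / 6, test = 1 / 6),
                     convention = "valve_intersection", write_images = FALSE)
  ts2 <- training_set(ds, 2L, view, max_frames_per_cine = 12L)
  model <- train_regressor(ts2$images, ts2$targets, configs$stage2)

  eu_b <- c(); eu_a <- c(); de <- c()
  for (s in ds$subjects) {
    if (s$split != "test") next
    d <- s$views[[view]]$data
    # convention-B ground truth: same geometry, points offset along the wall
    pars <- s$params$render[[view]]
    rp_b <- render_params(pixel_spacing_mm = unlist(pars$pixel_spacing_mm),
                          image_size = unlist(pars$image_size),
                          heart_rotation_deg = pars$heart_rotation_deg,
                          heart_center_px = unlist(pars$heart_center_px),
                          annulus_width_mm = pars$annulus_width_mm, view = view,
                          annotation_convention = "basal_myocardium",
                          convention_offset_mm = offset_mm)
    mo <- do.call(motion_profile_params, s$params$motion)
    gt_b <- render_cine(mo, rp_b, seed = s$views[[view]]$seed)$annotation

    pred <- stage2_refine(d$cine, d$annotation, model)$annotation
    sp <- d$cine$pixel_spacing
    eu_a <- c(eu_a, euclidean_error(pred, d$annotation, sp))
    eu_b <- c(eu_b, euclidean_error(pred, gt_b, sp))
    dp <- plane_displacement(pred, sp, rr_s = d$cine$rr_s)
    dg <- plane_displacement(gt_b, sp, rr_s = d$cine$rr_s)
    de <- c(de, displacement_error(dp, dg))
  }
  list(euclid_mean_mm = mean(eu_b), disp_err_abs_mean_mm = mean(abs(de)),
       within_convention_euclid_mm = mean(eu_a),
       n_test = sum(sapply(ds$subjects, function(s) s$split == "test")))
}
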