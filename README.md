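# mvtrack

Automated, time-resolved tracking of the mitral valve (MV) plane in
long-axis cine cardiac images, and derivation of the longitudinal
function metrics that depend on it.

## Who this is for

Quantifying left-ventricular longitudinal function from routine
long-axis cine imaging requires the two MV insertion points
(anterior/inferior in the two-chamber view, lateral/septal in the
four-chamber view) in *every* temporal frame.  Manual annotation takes
minutes per study and drifts between observers.  `mvtrack` implements a
dual-stage coarse-to-fine coordinate-regression pipeline that automates
the task, derives the clinical metrics from the tracked plane, and ships
a synthetic cine phantom generator with analytic ground truth so the
entire pipeline is testable end to end without any clinical data.

## The method

**Tracking.**  Per chamber view: (1) a coarse regressor predicts the two
points on every frame resized to a fixed 160 × 160 grid; (2) from the
coarse annotation an exactly invertible similarity transform is
estimated that standardizes the cine — 0.75 mm isotropic resolution,
valve plane horizontal with the anterior/lateral point on the left, apex
down, 118 × 162 crop centred on the valve; (3) a second regressor,
trained only on standardized crops, refines the points, which are mapped
back to the original grid through the exact inverse transform.  The
refinement is iterated once ("stage 1+2+2").  The regressors are
residual networks (a block-averaging stem plus fully-connected residual
blocks) trained with per-image median/IQR normalization,
keypoint-consistent augmentation, and mean-square error under Adam.

**Metrics.**  With `p1(t), p2(t)` the tracked points and `L0` the line
through the frame-0 (end-diastolic) points, the per-view displacement is

    d(t) = ( dist⊥(p1(t), L0) + dist⊥(p2(t), L0) ) / 2        [mm, apex-positive]

the resultant curve is the two-view mean, velocity is `v(t) = d'(t)`
(central differences, cm/s), and

    MAPSE = max d(t)
    s'    = first global velocity peak  (apex-directed, before MAPSE)
    e'    = second global velocity peak (return-directed, after MAPSE)
    a'    = third global velocity peak  (return-directed, after e')

**Agreement.**  Euclidean point error (mm), acute inter-plane angle
(deg), per-frame displacement error (mm), ICC(2,1) with 95 % CI,
Bland–Altman bias with ±1.96 sd limits, and linear regression — pooled
per pipeline stage by `stagewise_report()`.

## Worked example

Simulate one two-chamber phantom, derive the clinical metrics from its
ground-truth trajectory, and inspect the standardization the pipeline
would apply:

```r
library(mvtrack)

motion  <- motion_profile_params(mapse_mm = 14, hr_bpm = 72, n_frames = 30)
render  <- render_params(pixel_spacing_mm = 1.4, image_size = c(192, 192),
                         heart_rotation_deg = 210, view = "2ch")
phantom <- render_cine(motion, render, seed = 11)

phantom$cine
#> <mv_cine> 192 x 192 px, 30 frames, spacing 1.4 x 1.4 mm, RR 0.833 s, view 2ch

d <- plane_displacement(phantom$annotation, phantom$cine$pixel_spacing,
                        rr_s = phantom$cine$rr_s)
derive_metrics(d)
#> <mv_clinical_metrics> MAPSE 14.00 mm; s' 7.53, e' 7.92, a' 2.64 cm/s

estimate_standardization(phantom$annotation, phantom$cine)
#> <mv_transform> scale (1.867, 1.867), rotation 150 deg, translation (316.6, 110.8), output 118 x 162
```

MAPSE is recovered exactly (it is the generating parameter), and the
velocity peaks sit within a few percent of the analytic values of the
motion model (`analytic_velocity_peaks(motion)` gives 7.65, 8.20 and
2.73 cm/s — the residual is the attenuation of finite differences over
short velocity lobes).  The standardization rescales 1.4 mm pixels to
0.75 mm (scale 1.867) and rotates the 210°-oriented heart back to the
canonical pose.

To run the full study — simulate 240 subjects, train the four per-view
stage models, track the 40 held-out subjects and compute agreement —

```r
b <- benchmark_pipeline(n_subjects = 240, seed = 1)
b$report        # stage-wise Euclidean / angular / displacement errors
b$mapse_icc     # subject-level MAPSE ICC(2,1) vs ground truth
```

A command-line interface covering the same workflow
(`simulate`, `train`, `track`, `metrics`, `evaluate`) is installed at
`system.file("cli", "mvtrack", package = "mvtrack")`.

## Package layout

- `R/motion.R`, `R/render.R` — synthetic motion model and cine phantom
- `R/geometry.R` — similarity transforms, resize, standardization (`src/resample.cpp` holds the bicubic resampler)
- `R/regressor.R`, `R/training.R` — the landmark regressor and training recipes
- `R/pipeline.R` — `stage1_coarse()`, `stage2_refine()`, `track_mv()`
- `R/metrics.R` — displacement/velocity curves, MAPSE, s'/e'/a'
- `R/evaluation.R` — spatial error metrics, ICC, Bland–Altman, stage-wise report
- `R/io.R`, `R/cli.R` — NIfTI/PNG/CSV readers and writers, command-line interface
- `vignettes/mvtrack-methods.Rmd` — models, parameter choices and design notes
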