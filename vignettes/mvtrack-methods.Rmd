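---
title: "Dual-stage mitral valve plane tracking: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stage mitral valve plane tracking: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvtrack)
```

## The measurement problem

Longitudinal function of the left ventricle (LV) is summarized by how far
and how fast the mitral valve (MV) plane travels along the long axis over
the cardiac cycle.  Two clinical numbers condense this motion: MAPSE
(mitral annular plane systolic excursion, mm), the peak systolic
displacement of the plane towards the apex, and the LV early diastolic
velocity e' (cm/s), the second global peak of the displacement curve's
time derivative.  Deriving them from long-axis cine imaging requires the
two MV insertion points — anterior/inferior in the two-chamber view,
lateral/septal in the four-chamber view — to be localized in every
temporal frame.  Done by hand this takes minutes per study and is prone
to inconsistency; `mvtrack` automates it with a dual-stage coarse-to-fine
coordinate regression pipeline and derives the clinical metrics and a
full agreement-evaluation suite from the tracked plane.

## The pipeline

Each chamber view is processed independently, in three steps per cine:

1. **Coarse stage.**  Every frame is resampled to a fixed 160 x 160 grid
   (cubic interpolation, aspect ratio ignored, so pixels may become
   anisotropic) and a trained regressor predicts the two points per
   frame.  Predictions are mapped back to the original grid through the
   exact inverse of the resize transform.
2. **Automated standardization.**  From the coarse annotation a single
   similarity transform per cine is estimated that (i) rescales to
   0.75 mm isotropic resolution, (ii) rotates the frame-0 valve segment
   horizontal, first labelled point on the left and apex pointing down,
   and (iii) crops 118 rows x 162 columns around the frame-0 valve
   midpoint.  The transform is applied in one interpolation pass and is
   exactly invertible, so refined predictions return to the original
   pixel grid without accumulating resampling error.
3. **Refined stage + iteration.**  A second regressor, trained only on
   standardized crops, predicts the points on the standardized cine;
   they are mapped back through the inverse transform.  By default the
   refinement runs twice ("stage 1+2+2"), re-estimating the
   standardization from the latest annotation; further iterations do not
   improve accuracy.

The value of the middle step is variance reduction: the refinement model
never sees arbitrary orientations, resolutions or croppings, only a
narrow, canonical distribution, which is why a small model can be very
precise there.

### Coordinate conventions

All coordinates are 0-based with `x` the column index, `y` the row
index, pixel centres at integer positions and the origin at the top-left
pixel centre.  The crop centre of the 118 x 162 standard grid is the
continuous point `(x, y) = (80.5, 58.5)`.  The resize transform scales
by `output_size / input_size` per axis about the origin, so a 320 x 320
image maps the point (100, 60) to (50, 30).  Rotation is parameterized
about the frame-0 valve midpoint; with the translation free this choice
is arbitrary, and it keeps the numbers small.  Samples falling outside
the input field during resampling are zero-filled.  Resampling uses the
Catmull–Rom bicubic kernel throughout; only the coarse-stage resize
strictly requires cubic interpolation, and using one kernel everywhere
removes a needless degree of freedom.

### Determining the apex direction

The orientation step must resolve a 180-degree ambiguity: which side of
the valve plane is the apex.  The remaining frames' coarse annotations
carry that information, because the plane moves towards the apex during
systole.  We take the side of the frame-0 plane carrying the
*largest-magnitude* perpendicular excursion of the later frames' valve
midpoints.  A mean-offset statistic was tried first and proved fragile:
a coarse annotation with a systematic perpendicular bias comparable to
the mean excursion (entirely possible for a small model early in
training) flips the mean's sign and produces an upside-down crop that
the refinement model cannot recover from.  The extreme-excursion side is
invariant to such offsets as long as they stay below the excursion
itself.  The same rule fixes the sign of the displacement curve.  When
the observed motion is exactly in-plane the first-point-left orientation
decides.

### Refinement consistency guard

A refinement pass whose output moves the annotation further than any
plausible correction — more than 15 mm on average; legitimate
corrections are bounded by the coarse stage's own error, which is a few
millimetres — is treated like a failed pass: the previous stage's
annotation is kept and a warning is emitted.  The same fallback covers
passes that raise errors (for example a degenerate intermediate
annotation).  This keeps batch runs alive and, more importantly,
prevents a rare mis-standardized cine from contaminating subject-level
clinical metrics with tens of millimetres of error.

## The landmark regressor

Both stages use the same model family and training recipe: one grayscale
image in, four numbers out (`x1, y1, x2, y2`).  The backbone is a
residual network assembled from a block-averaging stem (a strided
average-pooling layer that turns the image into a coarse intensity grid)
followed by fully-connected residual blocks; `backbone = "tiny"` is the
first-class desk-scale configuration used by all tests and benchmarks,
and `backbone = "full"` is the same architecture deepened and widened.
No deep-learning framework is required: forward, backward and the Adam
optimizer are written in plain matrix algebra, which keeps the entire
train + predict path bit-reproducible on CPU given a seed.

Training follows the standard recipe: per-image intensity normalization
by median and interquartile range (a constant image falls back to
median subtraction with a warning), ten-fold keypoint-consistent
augmentation (scale within ±10 %, rotation within ±10°, translation
within ±3 px, drawn uniformly and applied identically to image and
target points), mean-square coordinate error optimized by Adam at
learning rate 1e-4 for 20 epochs with mini-batches of 8.  Those are the
`regressor_config()` defaults.  Internally targets live on a unit grid
for optimizer conditioning; the recorded loss history is converted to
squared pixels of the input grid.  Initializing the full backbone from
natural-image classification weights is a recognized option of the
recipe, but no such weights ship with this package, so
`pretrained = TRUE` raises an error and seeded random initialization is
the supported path.

### Desk-scale configurations

`default_stage_configs()` holds the configurations used by the package's
own benchmark (`benchmark_pipeline()`):

* stage 1 — pool 5 (a 32 x 32 stem grid), hidden width 192, 2 residual
  blocks, learning rate 1e-3, 28 epochs, batch 32, augmentation x3.
  The coarse model absorbs the full appearance variability (orientation
  0–360°, spacing 1.3–1.7 mm, field-of-view placement), so it gets the
  finer stem and the larger share of the training budget.
* stage 2 — pool 8, hidden 128, 2 blocks, 20 epochs, batch 32,
  augmentation x3 with the translation draw widened to ±16 px and
  rotation to ±15°.  Augmentation at this stage exists precisely to
  compensate the coarse stage's residual mis-centring; the widened draws
  match the error distribution of the tiny coarse model rather than that
  of a large one, and give the refinement a basin of attraction wide
  enough that the "stage 1+2+2" iteration converges from every coarse
  annotation we have observed.

Training uses at most 12 frames per cine, evenly spaced; temporally
adjacent frames are near-duplicates, so the cap trades negligible
diversity for a several-fold cost reduction.  Stage-2 training
standardizes each cine from its ground-truth annotation (teacher
forcing); tolerance to imperfect standardization at inference time comes
from the augmentation, not from training on corrupted transforms.

## The synthetic cine phantom

Because clinical cine data cannot be bundled, the package generates
long-axis phantoms with analytic ground truth.  Realism is explicitly a
non-goal; the phantom is designed so that (a) the valve plane is
detectable by an image-driven model, and (b) every variability axis of
routine clinical data that the pipeline must standardize away is
present.

### Motion model

MV plane displacement over one cycle is piecewise smooth with four
phases: systolic descent to the peak (MAPSE), early-diastolic recoil,
the diastasis plateau, and the atrial kick completing the return to the
end-diastolic plane.  Each moving phase is a half-cosine ramp, so the
velocity within a phase is a half-sine with closed-form peak
`A * pi / (2 T)` for amplitude `A` and duration `T`
(`analytic_velocity_peaks()` exposes these as the independent reference
for tests).  Parameters, with defaults chosen to sit in the middle of
adult clinical experience:

| parameter | default | range sampled per subject | meaning |
|---|---|---|---|
| `mapse_mm` | 12 | 8–18 | peak excursion; spans reduced to supra-normal function |
| `hr_bpm` | 60 | 50–90 | heart rate; sets the RR interval |
| `n_frames` | 30 | 25–50 | frames per reconstructed cycle |
| `systole_fraction` | 0.35 | 0.32–0.40 | cycle fraction at peak displacement |
| `diastasis_fraction` | 0.28 | 0.24–0.32 | fraction of diastole on the plateau |
| `atrial_kick_fraction_of_mapse` | 0.25 | 0.18–0.30 | share of the return completed by the kick |
| `noise_sd` | 0.03 | 0.02–0.05 | additive image noise (tissue intensities span ~0.15–0.9) |

The split of the non-plateau diastole between recoil and kick is fixed
at 0.52/0.48, which yields an e'/a' peak ratio of about 1.3 at the
defaults — ordinary for sinus rhythm.  Phase boundaries are snapped to
the frame grid (for six or more frames) so the sampled curve attains
MAPSE exactly at a frame; the analytic peak velocities are computed from
the snapped boundaries, i.e. for the profile as constructed.  Frames
span the full cycle inclusive of both endpoints, so frame times are
`i / (n - 1) * RR`.

### Appearance and ground truth

A stylized LV — bright blood pool inside a dark myocardial shell inside
a bright peri-cardiac fat band, with a dimmer atrial cavity above the
valve plane — translates rigidly along the long axis following the
motion profile.  Edges are smoothed over ~1.5 mm so that resampling and
learning see gradients rather than staircases.  The two MV points are
the analytic annulus endpoints, computed in continuous coordinates and
never read back from pixels, which is what makes sub-micrometre
round-trip assertions in the tests meaningful.  Per-subject rendering
draws resolution (1.3–1.7 mm), grid size, in-plane orientation (0–360°),
field-of-view placement and annulus width (26–34 mm) uniformly from the
ranges above; all randomness flows from one integer seed through a
splittable derivation, with no global RNG state left behind.

Two annotation conventions are supported, mirroring the two principles
human observers use: `valve_intersection` places ground truth at the
annulus endpoints; `basal_myocardium` offsets both points along the wall
towards the apex by `convention_offset_mm` (default 2 mm).  The offset
moves the reference plane but not the motion, so displacement curves and
MAPSE are identical between conventions — the mechanism behind the
observation that point-wise Euclidean error can be large between
conventions while displacement agreement stays good.  Per-point
annotation jitter is available as an additive knob but defaults to off;
no literature-derived magnitude exists for it, so tests do not rely on
it.

### What the phantom does not emulate

No bSSFP banding or surface-coil shading, no papillary muscles or
trabeculation, no through-plane motion, no arrhythmia (every cycle is
complete and periodic), no observer disagreement beyond the systematic
convention offset.  Passing the synthetic benchmarks therefore
demonstrates that the geometry is exact, the learning machinery works
and the pipeline's error budget holds under the stated variability —
not that clinical-grade accuracy is achieved on patient data.

## Clinical metric derivation

The per-view displacement is the average signed perpendicular distance
of the two MV points to the infinite line through the frame-0 points —
the end-diastolic reference plane, fixed for the whole cycle, not
re-fitted per frame.  The resultant curve is the frame-wise mean of the
two views, with the shorter curve linearly interpolated onto the
longer's time base when frame counts differ.  Velocity uses central
differences at interior samples and one-sided differences at the
endpoints, converted to cm/s.  When no frame timing is available, times
default to an RR of 1.0 s with a warning.

MAPSE is the maximum of the displacement curve.  The three velocity
peaks are resolved in time order with phase gating: s' is the
apex-directed peak before the MAPSE time, e' the largest-magnitude
return-directed local minimum after it, and a' the largest-magnitude
return-directed minimum after e'.  Pure global-magnitude ranking was
rejected because fused E/A waves would swap labels.  Discrete peaks are
refined by quadratic interpolation of the three neighbouring samples,
which removes most of the half-frame sampling bias; the residual
attenuation of a finite-difference derivative over a short lobe (a few
percent for the atrial kick at 30 frames/cycle) remains and is accepted.
A curve with a single smooth return (no atrial kick) yields e' with a'
flagged absent, and annotations with only two frames (end-diastole and
end-systole) yield MAPSE with all velocity metrics flagged unavailable.

## Agreement evaluation

Three spatial metrics compare a predicted annotation with ground truth:
per-point Euclidean distance in mm (anisotropic spacing respected),
the acute ("inner") angle between the two valve lines in degrees
(symmetric, invariant to swapping a line's endpoints, `NA` for
degenerate frames which are excluded listwise with counts reported), and
the signed per-frame difference between displacement curves.  Clinical
agreement uses ICC(2,1) — two-way random effects, absolute agreement,
single measures, with the 95 % confidence interval from the standard
F-distribution bounds — plus Bland–Altman bias with limits of agreement
at ±1.96 times the sample standard deviation of the differences, and
ordinary linear regression.  The ICC variant is recorded in the report
metadata so alternative variants remain comparable.

## Benchmark problem sizes

`benchmark_pipeline()` simulates 240 subjects (200 train, 40 test, split
by subject, never by frame), trains the four per-view stage models with
the desk-scale configurations, tracks the held-out subjects and reports
stage-wise spatial errors plus MAPSE and e' ICC from the resultant
curves.  `cross_convention_probe()` trains a refinement model under one
annotation convention on 50 subjects and evaluates against the other
convention's ground truth on 10 held-out subjects.  These sizes are the
package's benchmark definition: large enough that the coarse model
generalizes across the full orientation range and ICCs are estimated
from 40 independent subjects, small enough to run routinely on a single
CPU.

## Known limitations

* The tiny backbone is a capacity-limited stand-in; its coarse-stage
  error (a few mm on phantoms) is far above what a deep convolutional
  backbone achieves on clinical data, which is why the refinement basin
  had to be widened.
* Frames are processed independently; no temporal smoothing or recurrent
  modelling is attempted.
* DICOM input is not supported (no reader available in the package's
  dependency footprint); NIfTI and PNG-directory containers are.
* The phantom's schematic appearance means trained weights are useless
  for real images; the package's claim is about the pipeline, not the
  weights.
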