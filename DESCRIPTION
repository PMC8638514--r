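Package: mvtrack
Title: Dual-Stage Coarse-to-Fine Tracking of the Mitral Valve Plane in
    Long-Axis Cine Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated time-resolved localization of the two mitral valve
    insertion points in long-axis cine cardiac images using a dual-stage
    coarse-to-fine coordinate regression pipeline. A first regressor
    produces a coarse annotation on a fixed 160x160 grid; an automated,
    exactly invertible similarity transform then standardizes each cine
    to 0.75 mm isotropic resolution with the valve plane horizontal, the
    apex pointing down and a 118x162 crop centred on the valve, on which
    a second regressor refines the points before they are mapped back to
    the original image grid.  From the tracked plane the package derives
    mitral annular plane systolic excursion (MAPSE) and the global
    longitudinal velocity peaks s', e' and a', and provides the full
    agreement-evaluation suite (Euclidean, angular and plane-displacement
    errors, ICC(2,1) with confidence intervals, Bland-Altman limits of
    agreement, linear regression).  A synthetic cine phantom generator
    with analytic ground-truth trajectories makes the whole pipeline
    testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
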