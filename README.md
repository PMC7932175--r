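# rovstereo

Stereo-camera fish length measurement for mini-ROV reef surveys.

`rovstereo` is for fisheries and reef-ecology groups that measure fish from
paired underwater video collected with a small ROV: two action cameras
mounted on a baseline bar (406/610/762 mm separations, 10 degree toe-in,
narrow field of view at 1080p) plus a centre camera carrying a 75-mm
red-laser scaler (RLS). The package implements the full measurement chain —
checkerboard calibration, landmark triangulation, laser-scaler scaling —
together with the measurement-error analysis used to decide when each
system's estimates can be trusted, and a synthetic pool experiment that
regenerates the distance x angle-of-incidence x baseline validation design
so the whole pipeline is testable without any recorded video.

## The model

**Calibration (DLT).** Each camera is an 11-coefficient direct linear
transformation between world coordinates (mm) and pixels:

    u = (L1 x + L2 y + L3 z + L4) / d,   v = (L5 x + L6 y + L7 z + L8) / d,
    d = L9 x + L10 y + L11 z + 1

`calibrate_stereo()` estimates both cameras' coefficients from paired views
of a planar checkerboard (7 x 5 inner corners, 63.7 mm squares by default),
jointly with a 6-parameter rigid board pose per frame, by minimising the RMS
3-D distance between triangulated corners and the ideal board geometry.

**Fork length (SC).** `triangulate()` solves the stacked 4-equation linear
system from both cameras for each landmark; `fork_length()` returns the
Euclidean distance between the triangulated snout and tail-fork points.

**Laser scaler (RLS).** `rls_length()` computes
`(target px / laser px) * 75 mm` from on-screen Euclidean pixel distances.
On a target rotated by angle of incidence theta, this estimator carries an
irreducible foreshortening bias `PE -> 100 (cos theta - 1)` — the reason
laser measurements are restricted to near-perpendicular fish.

**Error analysis.** `percent_error()` is `100 (est - true) / true`;
`fit_gamma_glm()` fits `APE + 1` with a Gamma GLM (log link, dispersion
fixed at 1, i.e. exponential errors); `min_measurable_length()` inverts the
per-baseline fitted error curve at the 5% threshold,
`FL* = (log 6 - b0) / b1`. `filter_eligible()`, `validation_summary()`,
`length_frequency()` and `yield_comparison()` cover the field-survey
summaries.

## Worked example

Simulate a calibration session and one fish presentation (552 mm model at
3 m, 10 degrees off perpendicular, 0.5 px digitisation noise), then measure
it with both systems:

```r
library(rovstereo)

rig <- default_pool_rig(baseline_mm = 406)
frames <- simulate_calibration_session(rig, n_frames = 50, seed = 7,
                                       noise_sigma_px = 0.5)
cal <- calibrate_stereo(frames)
cal
#> <dlt_calibration> 50 frame pairs, reconstruction RMS 14.42 mm, k1 = (0, 0)

trial <- simulate_fish_trial(rig, distance_m = 3, aoi_deg = 10,
                             centered_on = 2, noise_sigma_px = 0.5, seed = 8)
px <- trial$sc[[2]]$reps[[1]]
est <- fork_length(
  landmark_observation(1, "snout", px$left[1, ], px$right[1, ]),
  landmark_observation(1, "fork",  px$left[2, ], px$right[2, ]),
  cal)
est$length_mm
#> [1] 549.3665
percent_error(est$length_mm, 552)
#> [1] -0.4770924

r <- trial$rls[[1]]
rls <- rls_length(r$target_px_len, r$laser_px_sep, r$lasers_on_target)
rls$length_mm
#> [1] 566.1174
percent_error(rls$length_mm, 552)
#> [1] 2.557492
```

The stereo estimate lands within half a percent of the true 552 mm. The
reconstruction RMS of ~14 mm is dominated by per-corner depth noise at the
far board placements, not by calibration bias: the same calibration keeps
known-length targets within a few tenths of a percent. A single laser
digitisation is much noisier (here +2.6%); averaged over replicates the RLS
settles onto its foreshortening bias, about -1.5% at 10 degrees. The full
factorial experiment is one call:

```r
design <- pool_design(trials = 3, n_digitizations = 23, noise_sigma_px = 0.5)
table <- run_pool_experiment(design)
summarize_cells(error_records(table))
```

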