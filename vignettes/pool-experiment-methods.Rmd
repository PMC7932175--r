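---
title: "Stereo-camera fish length measurement: model, simulator and error analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereo-camera fish length measurement: model, simulator and error analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rovstereo)
```

## The measurement problem

Fish length distributions are a workhorse quantity in reef ecology and stock
assessment, and video-based measurement avoids the selectivity and handling
mortality of capture gears. `rovstereo` implements the measurement chain of a
mini-ROV stereo-camera (SC) system — two action cameras in fixed housings on
a baseline bar, toed in toward the rig midline — together with the
traditional red laser scaler (RLS): two parallel lasers of known separation
projected from a centre camera. The package covers four stages:

1. **Calibration**: estimate, per camera, the 11 coefficients of a direct
   linear transformation (DLT) from paired views of a planar checkerboard of
   known square size.
2. **Measurement**: triangulate paired snout and tail-fork landmark pixels
   into 3-D points; their Euclidean distance is the fork-length (FL)
   estimate. The RLS alternative scales an on-screen fish length by the
   on-screen laser-dot separation.
3. **Error analysis**: percent error (PE) and absolute percent error (APE),
   per-cell summaries, a Gamma GLM with log link and fixed dispersion on
   `APE + 1`, and the minimum measurable length at a 5% error threshold.
4. **Survey summaries**: eligibility filtering, validation-object accuracy,
   30-mm length-frequency histograms and SC-vs-RLS yield comparison.

Because the package has no access to recorded video, a synthetic pool
experiment (`pool_design()`, `run_pool_experiment()`) regenerates the full
distance x angle-of-incidence x baseline trial design, so that every
downstream stage can be exercised and checked end to end.

## Geometry

World coordinates are millimetres with the origin at the midpoint between
the two stereo camera centres: +z points away from the vehicle toward
targets, +x toward the right camera, +y down. This makes the default rig
constructor a one-liner: cameras at `(+-baseline/2, 0, 0)` with yaw
`+-toe_in` (positive yaw swings the optical axis toward +x, so the left
camera's positive yaw is "toed in").

Intrinsics are derived from the camera's stated fields of view,

$$f = \frac{\mathrm{res}/2}{\tan(\mathrm{FOV}/2)},$$

applied per axis. The narrow-FOV setting used on the rig (64.6 deg
horizontal, 49.1 deg vertical at 1920 x 1080) yields different horizontal
and vertical pixel focal lengths (about 1518.6 and 1182.2 px), so
`camera_intrinsics()` carries `fx` and `fy` separately; the FOV pair is
taken as authoritative over the nominal "28 mm equivalent" focal length,
which over-determines the intrinsics. Radial distortion uses the
single-parameter model `r' = r (1 + k1 r^2)` on focal-normalised
coordinates, with `k1 = 0` by default: the narrow FOV is chosen in the field
precisely to minimise barrel distortion, and the simulator emulates
distortion-free optics. Projection is continuous; pixel quantisation is a
property of the digitisation noise model, not of the camera.

## Calibration

With the board's inner corners at known positions $\mathbf{x}$ on a plane,
the DLT relates world points to pixels by

$$u = \frac{L_1 x + L_2 y + L_3 z + L_4}{L_9 x + L_{10} y + L_{11} z + 1},
\qquad
v = \frac{L_5 x + L_6 y + L_7 z + L_8}{L_9 x + L_{10} y + L_{11} z + 1}.$$

`calibrate_stereo()` alternates two linear subproblems to estimate the
coefficient pair together with a 6-parameter rigid pose per frame:

* **Initialisation (closed form).** Each frame's board-to-image homography
  is estimated by normalised DLT. With the principal point fixed at the
  image centre and zero skew, the orthonormality constraints on the first
  two rotation columns identify `fx` and `fy` in closed form from the
  stacked homographies; per-frame extrinsics follow, and all poses are
  re-expressed in the frame-1 board frame, which defines the calibration's
  world frame (all derived lengths are invariant to this choice).
* **Refinement (alternation).** Given poses, the DLT coefficients are a
  linear least-squares solve over all stacked corners. Given coefficients,
  each corner pair is triangulated and each frame's pose updated by a
  Procrustes (Kabsch) fit of the ideal board onto its triangulated corners.
  The calibration error minimised and reported
  (`rms_reconstruction_mm`) is the RMS 3-D distance between triangulated
  corners and the ideal board geometry placed at the estimated poses.
  Iteration stops at a relative objective change of 1e-8 or 60 sweeps.

This closed-form-plus-alternation scheme was chosen over a derivative-free
pose search with random restarts: it is deterministic, has no tuning
parameters, and on noiseless synthetic sessions it recovers held-out point
geometry to better than 0.05 mm, which is the property the suite uses to
validate it. Degenerate inputs are refused: fewer than two frames, all
board poses identical, or a rank-deficient stacked design matrix. The
mirror-pose ambiguity of a planar target is resolved by requiring the board
in front of the cameras.

Two deliberate defaults deserve note:

* **Distortion search off by default.** A per-camera 1-D search for `k1`
  over [-0.05, 0.05] wraps the fit when `estimate_k1 = TRUE`. It is off by
  default because the optics modelled here are distortion-free by design,
  and on yaw-dominated board sessions the extra search adds variance and
  runtime without improving reconstruction.
* **Board wobble in the simulator.** The calibration-session simulator
  draws a small pitch/roll wobble (uniform +-10 deg) alongside the 0-20 deg
  yaw sweep. A hand- or pole-deployed board is never held perfectly
  yaw-only, and orientation diversity about more than one axis is also what
  renders the focal lengths identifiable from a planar target: with pure
  yaw the homography constraints are degenerate, and `calibrate_stereo()`
  reports exactly that.

## Triangulation and the two length estimators

`triangulate()` solves the 4-equation, 3-unknown linear system that the two
cameras' DLT relations impose on a matched pixel pair (ordinary least
squares on the rearranged `Ax = b` form, the standard reconstruction under
the 11-coefficient normalisation), and reports the RMS reprojection
residual; near-parallel ray systems (normal-matrix condition number above
1e12) are refused. `fork_length()` is the Euclidean distance between the
triangulated snout and fork landmarks, with quality equal to the larger of
the two reprojection RMS values.

The laser scaler is a ratio estimator:

$$\widehat{FL} = \frac{\text{target length on screen (px)}}
{\text{laser dot separation on screen (px)}} \times 75\,\mathrm{mm}.$$

On-screen lengths are Euclidean pixel distances in the centre camera's
image — the quantity an analyst actually measures on a still frame; the
estimator is invariant to rescaling both pixel quantities. Because the two
laser dots land at different depths on a rotated target while the fish
spans the same rotated plane, the estimator carries an irreducible
foreshortening bias: with ideal optics it converges to

$$\mathrm{PE} \to 100\,(\cos\theta - 1)$$

as distance grows, for angle of incidence (AOI) $\theta$ — about -1.5% at
10 deg but -6.0% at 20 deg. This is the mechanism behind the laser scaler's
tight eligibility window, and the simulator reproduces it within half a
percentage point at 2 m and beyond for the mid-sized model (the 890-mm
model needs about 3 m before the higher-order depth terms fade).

## The synthetic pool experiment

`pool_design()` fixes the study conditions: baselines 406/610/762 mm,
distances 1/2/3/5 m, AOI 0-40 deg in 5-deg steps, fish models of
288/552/890 mm FL, three replicate trials each with its own calibration
session of 50 frame pairs. Choices the design leaves open were set once:

* **Digitisation noise** is isotropic Gaussian with sigma = 0.5 px
  (quantisation to whole pixels available but off by default). Half a pixel
  is a realistic manual landmark-placement error at 1080p, and it places
  the simulated stereo errors inside the +-5% envelope through 30 deg AOI
  while leaving the far small-model cells the least certain — the same
  qualitative pattern the pool experiment shows.
* **Model stacking**: the three models share the display board, midlines
  stacked vertically 400 mm apart, and the board is presented once per
  model centring so each model is observed centred and one and two
  positions off-centre. This exercises the relative-position covariate and
  yields up to nine estimates per model and cell over three trials. The
  offset value itself is a config parameter; 400 mm keeps the outer models
  near the vertical FOV edge at 1 m, which is what produces the
  visibility clipping of the large model at close range.
* **Lasers** sit on the centre camera at the rig midline (zero toe-in and
  tilt), parallel to its optical axis, 75 mm apart; spot positions are exact
  ray-plane intersections.
* **AOI** rotates the board about the vertical axis only; pitch and roll of
  the display board are fixed at zero.

Visibility is determined on the noiseless projections: a model is
measurable by the stereo pair only when both landmarks are visible in both
views, and every unmeasurable flag traces to a specific invisible landmark.
At 1 m the narrow FOV clips the large model in most image slots — the
reproducible core of the close-range visibility losses observed with the
physical rig. (The physical experiment also showed baseline-specific
idiosyncrasies, e.g. losses at the shortest and widest baselines but not
the middle one; those arise from the six-camera mounting bar itself and are
outside a pinhole model.)

All randomness flows from a single integer seed; identical seeds give
byte-identical measurement tables.

## Error model

Percent error is $\mathrm{PE} = 100(\hat{L} - L)/L$ and APE its absolute
value. Cell summaries use Student-t 95% intervals on per-cell means (the
interval construction is a package choice; cells of one record carry an
undefined interval).

`fit_gamma_glm()` fits `APE + 1` with a Gamma GLM and log link. The `+1`
shift keeps the response strictly positive. The dispersion is fixed at 1 —
an exponential error model, appropriate for strictly positive data with
multiplicative errors — which affects only the Wald standard errors:
Gamma IRLS coefficient estimates are dispersion-free, and the package
asserts both behaviours. Fitting goes through `stats::glm` followed by a
Newton polish on the dispersion-free estimating equations, because IRLS
stops on a deviance criterion that leaves coefficients at roughly the
square root of the deviance tolerance; the polish takes them to machine
precision, where they are checked against an independently coded likelihood
maximiser. The default full-model design crosses system, distance and AOI,
with model length and relative position available as additional factors; no
multiplicity correction is applied (alpha = 0.05).

`min_measurable_length()` regresses `APE + 1` on fork length per baseline
(length continuous) and inverts the fitted curve at the threshold:

$$FL^* = \frac{\log(\mathrm{threshold} + 1) - b_0}{b_1},$$

i.e. the fitted mean of `APE + 1` equals 6 at a 5% threshold. The
alternative reading — comparing the fitted mean directly to 5 — is exposed
as `convention = "ape"`. A declining curve that starts below the threshold,
or a flat curve at or below it, is reported as "all lengths estimable"; a
flat curve above the threshold is not identifiable and errors.

## Survey summaries

Eligibility thresholds are data, not code: stereo records require both
landmarks visible in both views and AOI <= 25 deg (the conservative field
threshold backed by the 30-deg pool envelope); laser records require both
dots on the target and AOI <= 10 deg. Filtering partitions its input and
attaches exactly one primary reason code per exclusion (visibility and
laser-count outrank the AOI code). Length-frequency bins are half-open,
30 mm wide and anchored at 0 mm. Species labels are checked against a
bundled registry of the reef taxa recorded during the field surveys;
unknown names warn rather than error. Validation objects of known length
(603.3 / 364.0 / 274.6 mm PVC) summarise to per-site and pooled mean PE
with standard errors, grouped naturally by the calibration spanning each
site block. The published field dataset itself is not redistributable with
the package, so the survey functions are validated on synthetic fixtures
with known answers rather than on the printed site summaries.

## Problem sizes and numerical choices

The test suite and the acceptance script use problem sizes chosen to keep
Monte-Carlo standard errors well below the decision margins: 50-frame
calibration sessions; three calibration trials per baseline with repeated
digitisations bringing fully visible design cells to about 207 stereo
estimates (and 200 laser-scaler digitisations per cell); 1000 replicates
for the Wald-coverage property. Convergence and guard tolerances:
alternation 1e-8 relative (60-sweep cap), GLM deviance 1e-12 with Newton
polish to 1e-13 steps, triangulation condition limit 1e12, DLT
rank-deficiency guard at a singular-value ratio of 1e-10.

## Limitations

The simulator is an idealised pinhole world: no water refraction (a flat
port folds into the effective FOV), no fish body curvature (models are
rigid segments on a plane, as in the pool experiment), no motion blur,
synchronisation error or corner-detection failures, and digitisation noise
is homoscedastic in pixels. Passing its tests therefore demonstrates the
correctness of the measurement chain and the statistical machinery under
the stated noise model — not the field performance of any particular rig.
Real calibration sessions with purely yaw-rotated boards are refused by
design (focal lengths unidentifiable); sessions should include modest board
tilt, which hand deployment provides naturally.
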