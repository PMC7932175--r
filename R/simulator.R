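# Synthetic pool experiment: calibration sessions, fish-model presentations
# over the distance x AOI x baseline design, laser geometry, visibility
# clipping and digitization noise.

add_noise <- function(px, sigma, quantize) {
  if (sigma > 0) px <- px + matrix(stats::rnorm(length(px), 0, sigma), nrow(px))
  if (quantize) px <- round(px)
  px
}

#' Simulate a checkerboard calibration session
#'
#' Board poses are laid out on expanding concentric circles (clockwise)
#' across the stereo overlap, cycling over the distances 1/2/3/5 m, with the
#' angle of incidence drawn uniformly on 0-20 degrees about the vertical axis
#' plus small pitch/roll wobble (a hand- or pole-deployed board is never held
#' perfectly yaw-only; the wobble is also what renders the focal lengths
#' identifiable from a planar target). Frames in which any corner falls
#' outside either camera's sensor are resampled closer to the axis.
#'
#' @param rig A [default_pool_rig()]-style rig.
#' @param spec The [checkerboard_spec()].
#' @param n_frames Number of frame pairs to generate.
#' @param seed Integer seed; identical seeds give identical corner tables.
#' @param noise_sigma_px Isotropic Gaussian digitization noise, pixels.
#' @param quantize Round pixel coordinates to integers after adding noise.
#' @param distances_m Distances cycled over for board placement, m.
#' @param aoi_max_deg Maximum board yaw (angle of incidence), degrees.
#' @param tilt_max_deg Half-range of the uniform pitch/roll wobble, degrees.
#' @param max_attempts Resampling budget per frame before failing.
#' @return List of frame pairs (`frame_id`, `left`, `right` corner pixel
#'   matrices) with attributes `poses` (true board poses), `n_resampled` and
#'   `seed`.
#' @export
simulate_calibration_session <- function(rig, spec = checkerboard_spec(),
                                         n_frames = 50, seed = 1,
                                         noise_sigma_px = 0, quantize = FALSE,
                                         distances_m = c(1, 2, 3, 5),
                                         aoi_max_deg = 20, tilt_max_deg = 10,
                                         max_attempts = 1000) {
  stopifnot(n_frames >= 2)
  set.seed(seed)
  obj <- board_object_points(spec)
  obj_c <- sweep(obj, 2, colMeans(obj))  # board centred on its centroid
  intr <- rig$left$intrinsics
  tanH <- tan(intr$fov_h_deg * pi / 360)
  tanV <- tan(intr$fov_v_deg * pi / 360)
  frames <- vector("list", n_frames)
  poses <- vector("list", n_frames)
  n_resampled <- 0L
  per_ring <- 8L
  for (i in seq_len(n_frames)) {
    D <- distances_m[((i - 1L) %% length(distances_m)) + 1L] * 1000
    ring <- ((i - 1L) %/% per_ring) %% 4L          # expanding, then repeat
    ang <- -2 * pi * ((i - 1L) %% per_ring) / per_ring  # clockwise
    shrink <- 1
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      frac <- 0.55 * ring / 3 * shrink
      ctr <- c(frac * tanH * D * cos(ang) + stats::rnorm(1, 0, 0.03 * D),
               frac * tanV * D * sin(ang) + stats::rnorm(1, 0, 0.03 * D),
               D)
      pose <- board_pose(ctr,
                         yaw_deg = sample(c(-1, 1), 1) * stats::runif(1, 0, aoi_max_deg),
                         pitch_deg = stats::runif(1, -tilt_max_deg, tilt_max_deg),
                         roll_deg = stats::runif(1, -tilt_max_deg, tilt_max_deg))
      world <- apply_pose(pose, obj_c)
      pl <- project_points(world, rig$left)
      pr <- project_points(world, rig$right)
      if (all(pl$visible) && all(pr$visible)) {
        frames[[i]] <- list(frame_id = i,
                            left = add_noise(pl$px, noise_sigma_px, quantize),
                            right = add_noise(pr$px, noise_sigma_px, quantize))
        poses[[i]] <- pose
        ok <- TRUE
        break
      }
      n_resampled <- n_resampled + 1L
      shrink <- shrink * 0.7
    }
    if (!ok) {
      stop("FOV too narrow: no fully visible board pose found", call. = FALSE)
    }
  }
  attr(frames, "poses") <- poses
  attr(frames, "n_resampled") <- n_resampled
  attr(frames, "seed") <- seed
  frames
}

#' Fish display-board scene geometry
#'
#' Places the three paper fish models on a planar display board at a given
#' distance and angle of incidence (board yaw about the vertical axis), with
#' the models stacked vertically and the `centered_on` model's lateral
#' midline on the rig axis (the level at which the laser pair strikes the
#' board). Snout-fork separation equals each model's fork length exactly.
#'
#' @param distance_m Board distance from the rig, m.
#' @param aoi_deg Angle of incidence, degrees from perpendicular.
#' @param model_fl_mm Fork lengths of the stacked models, mm (small to large).
#' @param stack_mm Vertical separation between adjacent model midlines, mm.
#' @param centered_on Index (into `model_fl_mm`) of the model whose midline
#'   sits on the rig axis.
#' @param laser_sep_mm Laser-pair separation, mm.
#' @return List with per-model snout/fork world coordinates (`endpoints`,
#'   an n_models x 2 x 3 array, mm), laser spot coordinates (2 x 3),
#'   `on_target` laser count per the centred model, and scene metadata.
#' @export
fish_board_scene <- function(distance_m, aoi_deg,
                             model_fl_mm = c(288, 552, 890),
                             stack_mm = 400, centered_on = 2,
                             laser_sep_mm = 75) {
  th <- aoi_deg * pi / 180
  z0 <- distance_m * 1000
  axis <- c(cos(th), 0, -sin(th))  # board's in-plane horizontal direction
  n_m <- length(model_fl_mm)
  endpoints <- array(NA_real_, c(n_m, 2, 3))
  for (m in seq_len(n_m)) {
    y_m <- (m - centered_on) * stack_mm
    ctr <- c(0, y_m, z0)
    half <- model_fl_mm[m] / 2
    endpoints[m, 1, ] <- ctr + half * axis  # snout
    endpoints[m, 2, ] <- ctr - half * axis  # fork
  }
  xs <- c(-laser_sep_mm / 2, laser_sep_mm / 2)
  lasers <- cbind(xs, 0, z0 - xs * tan(th))  # intersection with board plane
  # along-axis position of each spot relative to the centred model's midline
  s <- xs / cos(th)
  on_target <- sum(abs(s) <= model_fl_mm[centered_on] / 2)
  list(endpoints = endpoints, lasers = lasers, on_target = on_target,
       distance_m = distance_m, aoi_deg = aoi_deg,
       model_fl_mm = model_fl_mm, centered_on = centered_on,
       stack_mm = stack_mm)
}

# project a scene through a rig: true (noiseless) pixels and visibility
project_scene <- function(rig, scene) {
  n_m <- dim(scene$endpoints)[1]
  pts <- matrix(aperm(scene$endpoints, c(3, 2, 1)), ncol = 3, byrow = TRUE)
  # rows: model 1 snout, model 1 fork, model 2 snout, ...
  pl <- project_points(pts, rig$left)
  pr <- project_points(pts, rig$right)
  pc <- project_points(pts, rig$center)
  sl <- project_points(scene$lasers, rig$center)
  idx <- function(m) c(2 * m - 1, 2 * m)
  list(
    pxL = pl$px, pxR = pr$px, pxC = pc$px,
    laser_pxC = sl$px,
    sc_measurable = vapply(seq_len(n_m), function(m)
      all(pl$visible[idx(m)]) && all(pr$visible[idx(m)]), logical(1)),
    rls_measurable = vapply(seq_len(n_m), function(m)
      m == scene$centered_on && scene$on_target == 2 &&
        all(pc$visible[idx(m)]) && all(sl$visible), logical(1)),
    vis_left = pl$visible, vis_right = pr$visible, vis_center = pc$visible,
    vis_laser = sl$visible
  )
}

#' Simulate one fish-presentation trial cell
#'
#' Builds the display-board scene for one (distance, AOI) cell, projects every
#' model's snout and fork into the left/right stereo cameras and the centre
#' (laser) camera, applies digitization noise, and returns the simulated
#' landmark observations, the RLS on-screen measurements for the centred
#' model, and a visibility report. Models with any landmark invisible in
#' either stereo view are flagged unmeasurable rather than erroring.
#'
#' @inheritParams fish_board_scene
#' @param rig A [default_pool_rig()]-style rig.
#' @param noise_sigma_px Gaussian digitization noise, pixels.
#' @param quantize Round noisy pixels to integers.
#' @param n_reps Number of independent digitizations.
#' @param seed Optional integer seed (set only when non-`NULL`).
#' @return List with `sc` (per-model, per-rep noisy landmark pixels and
#'   measurable flags), `rls` (per-rep `target_px_len`, `laser_px_sep`,
#'   `lasers_on_target`), `visibility` (tidy report) and the `scene`.
#' @export
simulate_fish_trial <- function(rig, distance_m, aoi_deg,
                                model_fl_mm = c(288, 552, 890),
                                stack_mm = 400, centered_on = 2,
                                noise_sigma_px = 0.5, quantize = FALSE,
                                n_reps = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scene <- fish_board_scene(distance_m, aoi_deg, model_fl_mm, stack_mm,
                            centered_on, rig$laser_baseline_mm)
  proj <- project_scene(rig, scene)
  n_m <- length(model_fl_mm)
  sc <- lapply(seq_len(n_m), function(m) {
    if (!proj$sc_measurable[m]) {
      return(list(measurable = FALSE))
    }
    rows <- c(2 * m - 1, 2 * m)
    reps <- lapply(seq_len(n_reps), function(r) {
      list(left = add_noise(proj$pxL[rows, , drop = FALSE], noise_sigma_px, quantize),
           right = add_noise(proj$pxR[rows, , drop = FALSE], noise_sigma_px, quantize))
    })
    list(measurable = TRUE, reps = reps)
  })
  rls <- NULL
  m0 <- scene$centered_on
  if (proj$rls_measurable[m0]) {
    rows <- c(2 * m0 - 1, 2 * m0)
    rls <- lapply(seq_len(n_reps), function(r) {
      ep <- add_noise(proj$pxC[rows, , drop = FALSE], noise_sigma_px, quantize)
      sp <- add_noise(proj$laser_pxC, noise_sigma_px, quantize)
      list(target_px_len = sqrt(sum((ep[1, ] - ep[2, ])^2)),
           laser_px_sep = sqrt(sum((sp[1, ] - sp[2, ])^2)),
           lasers_on_target = scene$on_target)
    })
  }
  model_lab <- rep(seq_len(n_m), each = 2)
  visibility <- tibble::tibble(
    model = rep(model_lab, 2),
    landmark = rep(rep(c("snout", "fork"), n_m), 2),
    camera = rep(c("left", "right"), each = 2 * n_m),
    visible = c(proj$vis_left, proj$vis_right)
  )
  list(sc = sc, rls = rls, visibility = visibility, scene = scene, proj = proj)
}

#' Pool experiment design
#'
#' The full factorial trial design of the pool experiment: stereo baselines
#' 406/610/762 mm, distances 1/2/3/5 m, angles of incidence 0-40 degrees in
#' 5-degree steps, fish models of 288/552/890 mm fork length, three replicate
#' calibration trials, and pixel-level digitization noise.
#'
#' @param baselines_mm,distances_m,aoi_deg,model_fl_mm Design grids.
#' @param trials Replicate trials (each trial re-runs the calibration).
#' @param n_digitizations Repeated digitizations per stereo image slot.
#' @param rls_digitizations Repeated digitizations per RLS image slot.
#' @param noise_sigma_px Gaussian digitization noise, pixels.
#' @param quantize Round noisy pixels to integers.
#' @param stack_mm Vertical separation between stacked model midlines, mm.
#' @param calibration_frames Checkerboard frame pairs per calibration.
#' @param seed Integer seed governing all randomness.
#' @return A list of class `pool_design`.
#' @export
pool_design <- function(baselines_mm = c(406, 610, 762),
                        distances_m = c(1, 2, 3, 5),
                        aoi_deg = seq(0, 40, 5),
                        model_fl_mm = c(288, 552, 890),
                        trials = 3, n_digitizations = 1,
                        rls_digitizations = 3,
                        noise_sigma_px = 0.5, quantize = FALSE,
                        stack_mm = 400, calibration_frames = 50, seed = 1) {
  stopifnot(length(baselines_mm) > 0, length(distances_m) > 0,
            length(aoi_deg) > 0, length(model_fl_mm) > 0,
            noise_sigma_px >= 0, trials >= 1)
  structure(list(baselines_mm = baselines_mm, distances_m = distances_m,
                 aoi_deg = aoi_deg, model_fl_mm = model_fl_mm,
                 trials = trials, n_digitizations = n_digitizations,
                 rls_digitizations = rls_digitizations,
                 noise_sigma_px = noise_sigma_px, quantize = quantize,
                 stack_mm = stack_mm, calibration_frames = calibration_frames,
                 seed = as.integer(seed)),
            class = "pool_design")
}

#' Run the synthetic pool experiment
#'
#' Simulates, per trial and baseline, a checkerboard calibration session and
#' the full distance x AOI grid of fish-model presentations (the board is
#' presented once per model centring, so each model is seen centred, one and
#' two positions off-centre). Stereo landmark pairs are digitized with noise
#' and triangulated through that trial's calibration; the red laser scaler is
#' simulated from the centre camera independently of baseline.
#'
#' @param design A [pool_design()].
#' @param rig_factory Function mapping a baseline (mm) to a rig.
#' @param estimate_k1 Passed to [calibrate_stereo()].
#' @param include_sc Simulate the stereo-camera measurements (and their
#'   calibrations).
#' @param include_rls Also simulate the red-laser-scaler measurements.
#' @return Tidy tibble: `trial`, `system`, `baseline_mm`, `distance_m`,
#'   `aoi_deg`, `true_fl_mm`, `rel_position`, `centered_on`, `replicate`,
#'   `est_fl_mm`, `quality`, `measurable`, `seed`. Unmeasurable image slots
#'   appear once with `est_fl_mm = NA`. Calibration failures mark the whole
#'   (trial, baseline) block excluded with a warning.
#' @export
run_pool_experiment <- function(design = pool_design(),
                                rig_factory = default_pool_rig,
                                estimate_k1 = FALSE, include_sc = TRUE,
                                include_rls = TRUE) {
  stopifnot(inherits(design, "pool_design"))
  set.seed(design$seed)
  cal_seeds <- matrix(
    sample.int(.Machine$integer.max / 2, design$trials * length(design$baselines_mm)),
    nrow = design$trials)
  rigs <- lapply(design$baselines_mm, rig_factory)
  names(rigs) <- as.character(design$baselines_mm)
  n_models <- length(design$model_fl_mm)
  cells <- expand.grid(distance_m = design$distances_m,
                       aoi_deg = design$aoi_deg,
                       centered_on = seq_len(n_models))
  # true projections per baseline x cell (independent of trial and noise)
  proj_cache <- lapply(seq_along(design$baselines_mm), function(bi) {
    lapply(seq_len(nrow(cells)), function(ci) {
      scene <- fish_board_scene(cells$distance_m[ci], cells$aoi_deg[ci],
                                design$model_fl_mm, design$stack_mm,
                                cells$centered_on[ci],
                                rigs[[bi]]$laser_baseline_mm)
      c(list(scene = scene), project_scene(rigs[[bi]], scene))
    })
  })
  out <- list()
  emit <- function(...) out[[length(out) + 1L]] <<- tibble::tibble(...)
  for (trial in seq_len(if (include_sc) design$trials else 0L)) {
    for (bi in seq_along(design$baselines_mm)) {
      b <- design$baselines_mm[bi]
      cal <- tryCatch({
        frames <- simulate_calibration_session(
          rigs[[bi]], checkerboard_spec(),
          n_frames = design$calibration_frames,
          seed = cal_seeds[trial, bi],
          noise_sigma_px = design$noise_sigma_px,
          quantize = design$quantize)
        calibrate_stereo(frames, resolution = rigs[[bi]]$left$intrinsics$resolution,
                         estimate_k1 = estimate_k1)
      }, error = function(e) {
        warning(sprintf("trial %d baseline %g: calibration failed (%s); block excluded",
                        trial, b, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(cal)) next
      for (ci in seq_len(nrow(cells))) {
        pc <- proj_cache[[bi]][[ci]]
        c_on <- cells$centered_on[ci]
        for (m in seq_len(n_models)) {
          rel_pos <- abs(m - c_on)
          if (!pc$sc_measurable[m]) {
            emit(trial = trial, system = "SC", baseline_mm = b,
                 distance_m = cells$distance_m[ci], aoi_deg = cells$aoi_deg[ci],
                 true_fl_mm = design$model_fl_mm[m], rel_position = rel_pos,
                 centered_on = c_on, replicate = NA_integer_,
                 est_fl_mm = NA_real_, quality = NA_real_,
                 measurable = FALSE, seed = design$seed)
            next
          }
          rows <- c(2 * m - 1, 2 * m)
          nr <- design$n_digitizations
          pxL <- pc$pxL[rep(rows, nr), , drop = FALSE]
          pxR <- pc$pxR[rep(rows, nr), , drop = FALSE]
          pxL <- add_noise(pxL, design$noise_sigma_px, design$quantize)
          pxR <- add_noise(pxR, design$noise_sigma_px, design$quantize)
          tri <- triangulate_many(pxL, pxR, cal$left_coeffs, cal$right_coeffs)
          p1 <- tri$points[seq(1, 2 * nr, 2), , drop = FALSE]
          p2 <- tri$points[seq(2, 2 * nr, 2), , drop = FALSE]
          lens <- sqrt(rowSums((p1 - p2)^2))
          qual <- pmax(tri$rms[seq(1, 2 * nr, 2)], tri$rms[seq(2, 2 * nr, 2)])
          emit(trial = trial, system = "SC", baseline_mm = b,
               distance_m = cells$distance_m[ci], aoi_deg = cells$aoi_deg[ci],
               true_fl_mm = design$model_fl_mm[m], rel_position = rel_pos,
               centered_on = c_on, replicate = seq_len(nr),
               est_fl_mm = lens, quality = qual,
               measurable = TRUE, seed = design$seed)
        }
      }
    }
  }
  if (include_rls) {
    for (ci in seq_len(nrow(cells))) {
      pc <- proj_cache[[1]][[ci]]  # centre camera identical across baselines
      m <- cells$centered_on[ci]
      if (!pc$rls_measurable[m]) {
        emit(trial = 1L, system = "RLS", baseline_mm = NA_real_,
             distance_m = cells$distance_m[ci], aoi_deg = cells$aoi_deg[ci],
             true_fl_mm = design$model_fl_mm[m], rel_position = 0L,
             centered_on = m, replicate = NA_integer_,
             est_fl_mm = NA_real_, quality = NA_real_,
             measurable = FALSE, seed = design$seed)
        next
      }
      rows <- c(2 * m - 1, 2 * m)
      nr <- design$rls_digitizations
      ep <- add_noise(pc$pxC[rep(rows, nr), , drop = FALSE],
                      design$noise_sigma_px, design$quantize)
      sp <- add_noise(pc$laser_pxC[rep(1:2, nr), , drop = FALSE],
                      design$noise_sigma_px, design$quantize)
      d_ep <- sqrt(rowSums((ep[seq(1, 2 * nr, 2), , drop = FALSE] -
                              ep[seq(2, 2 * nr, 2), , drop = FALSE])^2))
      d_sp <- sqrt(rowSums((sp[seq(1, 2 * nr, 2), , drop = FALSE] -
                              sp[seq(2, 2 * nr, 2), , drop = FALSE])^2))
      emit(trial = 1L, system = "RLS", baseline_mm = NA_real_,
           distance_m = cells$distance_m[ci], aoi_deg = cells$aoi_deg[ci],
           true_fl_mm = design$model_fl_mm[m], rel_position = 0L,
           centered_on = m, replicate = seq_len(nr),
           est_fl_mm = d_ep / d_sp * rigs[[1]]$laser_baseline_mm,
           quality = 2, measurable = TRUE, seed = design$seed)
    }
  }
  dplyr::bind_rows(out)
}
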