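# Shared fixtures, built once per test run.
#
# Calibrations are the expensive objects; the suite shares one noiseless and
# one noisy (0.5 px) session per baseline of interest.

rig_bd1 <- default_pool_rig(406)
rig_bd3 <- default_pool_rig(762)

cal_noiseless_bd1 <- calibrate_stereo(
  simulate_calibration_session(rig_bd1, n_frames = 12, seed = 101,
                               noise_sigma_px = 0))
cal_noiseless_bd3 <- calibrate_stereo(
  simulate_calibration_session(rig_bd3, n_frames = 12, seed = 101,
                               noise_sigma_px = 0))
frames_noisy_bd1 <- simulate_calibration_session(rig_bd1, n_frames = 50,
                                                 seed = 202,
                                                 noise_sigma_px = 0.5)
cal_noisy_bd1 <- calibrate_stereo(frames_noisy_bd1)

# measure one model's fork length through a calibration, optionally with
# many replicated noisy digitizations (vectorised); returns lengths in mm
fork_lengths_through <- function(rig, cal, distance_m, aoi_deg, model = 2,
                                 sigma = 0, n = 1, centered_on = model) {
  tr <- simulate_fish_trial(rig, distance_m, aoi_deg, centered_on = centered_on,
                            noise_sigma_px = 0, n_reps = 1)
  if (!tr$sc[[model]]$measurable) return(numeric(0))
  px <- tr$sc[[model]]$reps[[1]]
  pxL <- px$left[rep(1:2, n), , drop = FALSE]
  pxR <- px$right[rep(1:2, n), , drop = FALSE]
  if (sigma > 0) {
    pxL <- pxL + matrix(rnorm(length(pxL), 0, sigma), nrow(pxL))
    pxR <- pxR + matrix(rnorm(length(pxR), 0, sigma), nrow(pxR))
  }
  tri <- rovstereo:::triangulate_many(pxL, pxR, cal$left_coeffs, cal$right_coeffs)
  p1 <- tri$points[seq(1, 2 * n, 2), , drop = FALSE]
  p2 <- tri$points[seq(2, 2 * n, 2), , drop = FALSE]
  sqrt(rowSums((p1 - p2)^2))
}
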