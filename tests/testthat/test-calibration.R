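test_that("board object points form the stated planar grid", {
  pts <- board_object_points(checkerboard_spec(2, 2, 10))
  expect_equal(pts, cbind(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10), z = 0),
               ignore_attr = TRUE)
  pts <- board_object_points(checkerboard_spec())
  expect_equal(nrow(pts), 35)
  expect_equal(diff(range(pts[, 1])), 6 * 63.7)   # 382.2 mm
  expect_equal(diff(range(pts[, 2])), 4 * 63.7)   # 254.8 mm
  # row-major indexing: (row 1, col 3) zero-based -> (3, 1) * 63.7
  expect_equal(unname(pts[1 * 7 + 3 + 1, ]), c(3 * 63.7, 1 * 63.7, 0))
})

test_that("DLT projection agrees with the pinhole model it encodes", {
  cam <- rov_camera(camera_intrinsics(c(1920, 1080), 64.6, 49.1),
                    camera_pose(c(-203, 5, -2), yaw_deg = 10, pitch_deg = 1))
  coeffs <- dlt_from_camera(cam)
  set.seed(21)
  pts <- cbind(runif(20, -600, 600), runif(20, -350, 350), runif(20, 800, 5200))
  expect_equal(dlt_project(pts, coeffs),
               project_points(pts, cam)$px,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("DLT degenerates as documented", {
  # affine camera: zero projective row makes u, v linear in the point
  aff <- c(2, 0, 0, 10, 0, 3, 0, 20, 0, 0, 0)
  p1 <- dlt_project(c(1, 1, 1), aff)
  p2 <- dlt_project(c(2, 1, 1), aff)
  p3 <- dlt_project(c(3, 1, 1), aff)
  expect_equal(p3 - p2, p2 - p1)
  # vanishing denominator
  bad <- c(rep(0, 8), 0, 0, -1)  # d = 1 - z
  expect_error(dlt_project(c(0, 0, 1), bad), "projection plane")
})

test_that("noiseless calibration identifies the geometry", {
  expect_lt(cal_noiseless_bd1$rms_reconstruction_mm, 0.1)
  # held-out points: project through the true rig, triangulate through the
  # fitted calibration, rigidly align, compare
  set.seed(33)
  pts <- cbind(runif(30, -400, 400), runif(30, -250, 250), runif(30, 1000, 5000))
  pl <- project_points(pts, rig_bd1$left)
  pr <- project_points(pts, rig_bd1$right)
  keep <- pl$visible & pr$visible
  tri <- rovstereo:::triangulate_many(pl$px[keep, ], pr$px[keep, ],
                                      cal_noiseless_bd1$left_coeffs,
                                      cal_noiseless_bd1$right_coeffs)$points
  fit <- rovstereo:::kabsch(tri, pts[keep, ])
  aligned <- rovstereo:::apply_pose(fit, tri)
  expect_lt(max(sqrt(rowSums((aligned - pts[keep, ])^2))), 0.05)
})

test_that("degenerate sessions are refused", {
  frames <- simulate_calibration_session(rig_bd1, n_frames = 2, seed = 5)
  expect_error(calibrate_stereo(frames[1]), "insufficient frames")
  same <- list(frames[[1]], frames[[1]])
  expect_error(calibrate_stereo(same), "degenerate geometry")
})

test_that("reconstruction error grows with corner noise", {
  med_rms <- vapply(c(0, 0.25, 0.5, 1.0), function(sigma) {
    median(vapply(1:5, function(s) {
      frames <- simulate_calibration_session(rig_bd1, n_frames = 10,
                                             seed = 400 + s,
                                             noise_sigma_px = sigma)
      calibrate_stereo(frames)$rms_reconstruction_mm
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_rms) >= 0))
})

test_that("noisy calibration keeps the metric scale within 0.5%", {
  # noiseless known-length targets triangulated through the noisy calibration
  errs <- unlist(lapply(c(2, 3), function(d) {
    vapply(2:3, function(m) {
      fork_lengths_through(rig_bd1, cal_noisy_bd1, d, 0, model = m)
    }, numeric(1))
  }))
  true_fl <- rep(c(552, 890), 2)
  expect_lt(max(abs(percent_error(errs, true_fl))), 0.5)
})

test_that("more calibration frames do not hurt reconstruction", {
  # paired seeds; metric: aligned residual of held-out noiseless points
  set.seed(1)
  pts <- cbind(runif(40, -400, 400), runif(40, -250, 250), runif(40, 1000, 5000))
  pl <- project_points(pts, rig_bd1$left)
  pr <- project_points(pts, rig_bd1$right)
  keep <- pl$visible & pr$visible
  metric <- function(cal) {
    tri <- rovstereo:::triangulate_many(pl$px[keep, ], pr$px[keep, ],
                                        cal$left_coeffs, cal$right_coeffs)$points
    fit <- rovstereo:::kabsch(tri, pts[keep, ])
    sqrt(mean(rowSums((rovstereo:::apply_pose(fit, tri) - pts[keep, ])^2)))
  }
  err <- sapply(1:7, function(s) {
    vapply(c(8, 50), function(nf) {
      frames <- simulate_calibration_session(rig_bd1, n_frames = nf,
                                             seed = 700 + s,
                                             noise_sigma_px = 0.5)
      metric(calibrate_stereo(frames))
    }, numeric(1))
  })
  expect_lte(median(err[2, ]), median(err[1, ]))
})

test_that("calibration files round-trip exactly and corner tables closely", {
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal_noisy_bd1, path)
  back <- read_calibration(path)
  expect_identical(back$left_coeffs, cal_noisy_bd1$left_coeffs)
  expect_identical(back$right_coeffs, cal_noisy_bd1$right_coeffs)
  expect_identical(back$rms_reconstruction_mm, cal_noisy_bd1$rms_reconstruction_mm)
  expect_equal(back$spec, cal_noisy_bd1$spec)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_corner_table(frames_noisy_bd1[1:3], csv)
  frames2 <- read_corner_table(csv)
  expect_equal(frames2[[2]]$left, frames_noisy_bd1[[2]]$left,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(frames2[[3]]$right, frames_noisy_bd1[[3]]$right,
               tolerance = 1e-9, ignore_attr = TRUE)
})
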