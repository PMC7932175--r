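test_that("triangulation round-trips a projected point exactly", {
  cal <- cal_noiseless_bd1
  # a point expressed in the calibration's own world frame
  pt <- c(120, -40, 2600)
  pl <- dlt_project(pt, cal$left_coeffs)
  pr <- dlt_project(pt, cal$right_coeffs)
  out <- triangulate(pl, pr, cal)
  expect_equal(out$point, pt, tolerance = 1e-6)
  expect_lt(out$rms, 1e-6)
})

test_that("triangulation matches a brute-force reprojection minimizer", {
  cal <- cal_noiseless_bd1
  pt <- c(-80, 60, 2100)
  set.seed(77)
  pl <- dlt_project(pt, cal$left_coeffs) + rnorm(2, 0, 0.5)
  pr <- dlt_project(pt, cal$right_coeffs) + rnorm(2, 0, 0.5)
  out <- triangulate(pl, pr, cal)
  # independent oracle: 3-level refined lattice search over world space,
  # minimizing summed squared reprojection error
  cost <- function(p) {
    sum((dlt_project(p, cal$left_coeffs) - pl)^2) +
      sum((dlt_project(p, cal$right_coeffs) - pr)^2)
  }
  ctr <- pt
  span <- 50
  for (level in 1:3) {
    g <- expand.grid(x = ctr[1] + seq(-span, span, length.out = 21),
                     y = ctr[2] + seq(-span, span, length.out = 21),
                     z = ctr[3] + seq(-span, span, length.out = 21))
    costs <- apply(as.matrix(g), 1, cost)
    ctr <- as.numeric(g[which.min(costs), ])
    span <- span / 8
  }
  expect_equal(out$point, ctr, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("contradictory pixel pairs surface as large reprojection error", {
  # an identical off-axis pixel in both views of a wide-baseline rig cannot
  # come from any single world point
  cal <- cal_noiseless_bd3
  px <- c(1500, 700)
  out <- triangulate(px, px, cal)
  expect_gt(out$rms, 5)
})

test_that("fork length recovers model lengths exactly without noise", {
  for (case in list(list(fl = 1, d = 2, aoi = 0, rig = rig_bd1, cal = cal_noiseless_bd1),
                    list(fl = 3, d = 3, aoi = 30, rig = rig_bd1, cal = cal_noiseless_bd1))) {
    tr <- simulate_fish_trial(case$rig, case$d, case$aoi,
                              centered_on = case$fl, noise_sigma_px = 0)
    px <- tr$sc[[case$fl]]$reps[[1]]
    est <- fork_length(
      landmark_observation(1, "snout", px$left[1, ], px$right[1, ]),
      landmark_observation(1, "fork", px$left[2, ], px$right[2, ]),
      case$cal)
    expect_equal(est$length_mm, c(288, 552, 890)[case$fl], tolerance = 1e-3)
  }
  expect_error(fork_length(landmark_observation(1, "snout", c(1, 1), c(2, 2)),
                           landmark_observation(2, "fork", c(1, 1), c(2, 2)),
                           cal_noiseless_bd1),
               "frame mismatch")
})

test_that("noiseless fork length is invariant to AOI and distance", {
  worst <- 0
  for (d in c(1, 2, 3, 5)) {
    for (aoi in seq(0, 40, 10)) {
      lens <- fork_lengths_through(rig_bd1, cal_noiseless_bd1, d, aoi,
                                   model = 2)
      if (length(lens)) worst <- max(worst, abs(lens - 552))
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("laser-scaler arithmetic and eligibility rules hold", {
  expect_equal(rls_length(200, 200)$length_mm, 75)
  expect_equal(rls_length(1104, 150)$length_mm, 552)
  # scale equivariance: doubling every pixel quantity changes nothing
  expect_equal(rls_length(2 * 1104, 2 * 150)$length_mm, 552)
  expect_error(rls_length(1104, 150, lasers_on_target = 1), "ineligible: lasers")
  expect_error(rls_length(1104, 0), "zero laser separation")
})

test_that("simulated laser-scaler bias follows the foreshortening law", {
  # PE -> 100 (cos theta - 1) at distance >= 2 m, within 0.5 points
  for (aoi in c(0, 10, 20, 30)) {
    for (d in c(2, 5)) {
      tr <- simulate_fish_trial(rig_bd1, d, aoi, centered_on = 2,
                                noise_sigma_px = 0)
      r <- tr$rls[[1]]
      pe <- percent_error(r$target_px_len / r$laser_px_sep * 75, 552)
      expect_lt(abs(pe - 100 * (cos(aoi * pi / 180) - 1)), 0.5)
    }
  }
  # the large model's published worked case: 890 mm at 20 degrees scales to
  # roughly 836 mm on screen
  tr <- simulate_fish_trial(rig_bd1, 3, 20, centered_on = 3, noise_sigma_px = 0)
  r <- tr$rls[[1]]
  expect_equal(r$target_px_len / r$laser_px_sep * 75, 890 * cos(20 * pi / 180),
               tolerance = 0.005)
})

test_that("stereo noise grows with distance and shrinks with baseline", {
  ape_cell <- function(rig, cal, d) {
    set.seed(900 + d)
    lens <- fork_lengths_through(rig, cal, d, 0, model = 2, sigma = 0.5,
                                 n = 200)
    median(abs(percent_error(lens, 552)))
  }
  by_distance <- vapply(c(1, 2, 3, 5), function(d)
    ape_cell(rig_bd1, cal_noiseless_bd1, d), numeric(1))
  expect_true(all(diff(by_distance) > 0))
  expect_lte(ape_cell(rig_bd3, cal_noiseless_bd3, 5),
             ape_cell(rig_bd1, cal_noiseless_bd1, 5))
})

test_that("long-format landmark tables measure per frame", {
  tr <- simulate_fish_trial(rig_bd1, 2, 10, centered_on = 2, noise_sigma_px = 0)
  px <- tr$sc[[2]]$reps[[1]]
  tab <- tibble::tibble(
    frame_id = 1,
    landmark = rep(c("snout", "fork"), 2),
    camera = rep(c("left", "right"), each = 2),
    u = c(px$left[, 1], px$right[, 1]),
    v = c(px$left[, 2], px$right[, 2]))
  out <- measure_fork_lengths(tab, cal_noiseless_bd1)
  expect_equal(out$length_mm, 552, tolerance = 1e-3)
})
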