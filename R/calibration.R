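# Stereo calibration from paired checkerboard views.
#
# Pipeline: per-frame plane-to-image homographies -> closed-form focal
# recovery (fixed principal point) -> per-frame board poses expressed in the
# frame-1 board frame -> alternating refinement (linear DLT solve given
# poses; triangulation + Procrustes pose update given the DLT). The reported
# calibration error is the RMS 3D distance between triangulated corners and
# the ideal board geometry placed at the estimated poses.

# homography mapping board-plane (x, y) [mm] to pixels, by normalised DLT
homography_from_plane <- function(board_xy, px) {
  n <- nrow(board_xy)
  stopifnot(n >= 4, nrow(px) == n)
  norm_T <- function(pts) {
    c0 <- colMeans(pts)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(pts, 2, c0)^2)))
    matrix(c(s, 0, 0, 0, s, 0, -s * c0[1], -s * c0[2], 1), 3, 3)
  }
  T1 <- norm_T(board_xy)
  T2 <- norm_T(px)
  xh <- cbind(board_xy, 1) %*% t(T1)
  uh <- cbind(px, 1) %*% t(T2)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(xh, 0, 0, 0, -uh[, 1] * xh)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, xh, -uh[, 2] * xh)
  h <- svd(A)$v[, 9]
  H <- solve(T2) %*% matrix(h, 3, 3, byrow = TRUE) %*% T1
  H / H[3, 3]
}

# closed-form per-axis focal lengths from plane homographies, principal point
# fixed at `pp`, zero skew: solve for b = (1/fx^2, 1/fy^2, 1) up to scale from
# the orthonormality constraints on the first two rotation columns.
zhang_focal_fixed_pp <- function(H_list, pp) {
  rows <- lapply(H_list, function(H) {
    # shift pixel origin to the principal point
    Tc <- matrix(c(1, 0, 0, 0, 1, 0, -pp[1], -pp[2], 1), 3, 3)
    Hc <- Tc %*% H
    h1 <- Hc[, 1]; h2 <- Hc[, 2]
    rbind(h1 * h2, h1^2 - h2^2)
  })
  M <- do.call(rbind, rows)
  sv <- svd(M)
  b <- sv$v[, 3]
  if (b[3] < 0) b <- -b
  if (b[1] <= 0 || b[2] <= 0 || sv$d[2] / sv$d[1] < 1e-10) {
    stop("degenerate geometry: board orientations do not identify the focal lengths",
         call. = FALSE)
  }
  c(fx = sqrt(b[3] / b[1]), fy = sqrt(b[3] / b[2]))
}

# board pose relative to one camera from its homography and intrinsics
extrinsics_from_homography <- function(H, fx, fy, pp) {
  Kinv <- matrix(c(1 / fx, 0, 0, 0, 1 / fy, 0,
                   -pp[1] / fx, -pp[2] / fy, 1), 3, 3)
  A <- Kinv %*% H
  lam <- 2 / (sqrt(sum(A[, 1]^2)) + sqrt(sum(A[, 2]^2)))
  if (A[3, 3] < 0) A <- -A  # board must lie in front of the camera
  r1 <- lam * A[, 1]; r2 <- lam * A[, 2]
  R0 <- cbind(r1, r2, c(r1[2] * r2[3] - r1[3] * r2[2],
                        r1[3] * r2[1] - r1[1] * r2[3],
                        r1[1] * r2[2] - r1[2] * r2[1]))
  s <- svd(R0)
  R <- s$u %*% diag(c(1, 1, det(s$u %*% t(s$v)))) %*% t(s$v)
  list(R = R, t = lam * A[, 3])
}

# linear least-squares DLT solve: world n x 3, px n x 2 -> 11 coefficients
dlt_solve <- function(world, px) {
  n <- nrow(world)
  A <- matrix(0, 2 * n, 11)
  X <- world[, 1]; Y <- world[, 2]; Z <- world[, 3]
  u <- px[, 1]; v <- px[, 2]
  A[seq(1, 2 * n, 2), ] <- cbind(X, Y, Z, 1, 0, 0, 0, 0, -u * X, -u * Y, -u * Z)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, 0, X, Y, Z, 1, -v * X, -v * Y, -v * Z)
  b <- as.numeric(t(cbind(u, v)))
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[11] / sv[1] < 1e-10) {
    stop("degenerate geometry: DLT design matrix is rank-deficient", call. = FALSE)
  }
  as.numeric(qr.solve(A, b))
}

#' Forward DLT projection
#'
#' Projects world points through an 11-coefficient direct linear
#' transformation: `u = (L1 x + L2 y + L3 z + L4) / d`,
#' `v = (L5 x + L6 y + L7 z + L8) / d` with `d = L9 x + L10 y + L11 z + 1`.
#'
#' @param p Numeric 3-vector or n x 3 matrix of world points (mm).
#' @param coeffs Numeric 11-vector of DLT coefficients.
#' @return n x 2 matrix of pixels.
#' @export
dlt_project <- function(p, coeffs) {
  p <- rbind(p)
  stopifnot(length(coeffs) == 11, ncol(p) == 3)
  d <- p %*% coeffs[9:11] + 1
  if (any(abs(d) < 1e-12)) {
    stop("point on projection plane: DLT denominator vanishes", call. = FALSE)
  }
  u <- (p %*% coeffs[1:3] + coeffs[4]) / d
  v <- (p %*% coeffs[5:7] + coeffs[8]) / d
  cbind(u = as.numeric(u), v = as.numeric(v))
}

#' DLT coefficients of an ideal pinhole camera
#'
#' Converts a [rov_camera()] (ignoring distortion) to the equivalent
#' 11-coefficient DLT, normalising the projective scale so the 12th entry is
#' one. Cameras whose projection-plane term vanishes at the world origin (for
#' example a camera at the origin looking along +z) cannot be normalised.
#'
#' @param camera A [rov_camera()] object.
#' @return Numeric 11-vector.
#' @export
dlt_from_camera <- function(camera) {
  intr <- camera$intrinsics
  K <- matrix(c(intr$fx, 0, 0, 0, intr$fy, 0,
                intr$principal_point[1], intr$principal_point[2], 1), 3, 3)
  Rt <- t(camera$pose$R)
  P <- K %*% cbind(Rt, -Rt %*% camera$pose$position)
  if (abs(P[3, 4]) < 1e-12) {
    stop("camera cannot be expressed in normalised DLT form (P[3,4] = 0)",
         call. = FALSE)
  }
  P <- P / P[3, 4]
  c(P[1, ], P[2, ], P[3, 1:3])
}

# vectorised two-view triangulation: solves the stacked 4 x 3 linear system
# per point via closed-form 3x3 normal equations. Returns n x 3 points and the
# RMS reprojection residual (over the 4 pixel components) per point.
triangulate_many <- function(pxL, pxR, Lc, Rc) {
  uL <- pxL[, 1]; vL <- pxL[, 2]
  uR <- pxR[, 1]; vR <- pxR[, 2]
  # rows: a*X = b with a = (c1 - u c9, c2 - u c10, c3 - u c11), b = u - c4
  row_of <- function(u, c14, c9_11) {
    list(a1 = c14[1] - u * c9_11[1],
         a2 = c14[2] - u * c9_11[2],
         a3 = c14[3] - u * c9_11[3],
         b = u - c14[4])
  }
  r1 <- row_of(uL, Lc[1:4], Lc[9:11])
  r2 <- row_of(vL, Lc[5:8], Lc[9:11])
  r3 <- row_of(uR, Rc[1:4], Rc[9:11])
  r4 <- row_of(vR, Rc[5:8], Rc[9:11])
  rows <- list(r1, r2, r3, r4)
  acc <- function(f) Reduce(`+`, lapply(rows, f))
  m11 <- acc(function(r) r$a1 * r$a1)
  m12 <- acc(function(r) r$a1 * r$a2)
  m13 <- acc(function(r) r$a1 * r$a3)
  m22 <- acc(function(r) r$a2 * r$a2)
  m23 <- acc(function(r) r$a2 * r$a3)
  m33 <- acc(function(r) r$a3 * r$a3)
  g1 <- acc(function(r) r$a1 * r$b)
  g2 <- acc(function(r) r$a2 * r$b)
  g3 <- acc(function(r) r$a3 * r$b)
  det3 <- m11 * (m22 * m33 - m23^2) - m12 * (m12 * m33 - m23 * m13) +
    m13 * (m12 * m23 - m22 * m13)
  i11 <- (m22 * m33 - m23^2) / det3
  i12 <- (m13 * m23 - m12 * m33) / det3
  i13 <- (m12 * m23 - m13 * m22) / det3
  i22 <- (m11 * m33 - m13^2) / det3
  i23 <- (m12 * m13 - m11 * m23) / det3
  i33 <- (m11 * m22 - m12^2) / det3
  X <- i11 * g1 + i12 * g2 + i13 * g3
  Y <- i12 * g1 + i22 * g2 + i23 * g3
  Z <- i13 * g1 + i23 * g2 + i33 * g3
  res2 <- Reduce(`+`, lapply(rows, function(r) {
    (r$a1 * X + r$a2 * Y + r$a3 * Z - r$b)^2
  }))
  list(points = cbind(X, Y, Z), rms = sqrt(res2 / 4))
}

# internal fit at fixed distortion: returns coefficients, poses and rms
fit_dlt_given_k1 <- function(frames, obj_pts, resolution, k1 = c(0, 0),
                             intr_ref = NULL, max_sweeps = 60, tol = 1e-8) {
  pp <- resolution / 2
  undistorted <- lapply(frames, function(fr) {
    if (all(k1 == 0) || is.null(intr_ref)) return(fr)
    fr$left <- undistort_pixels(fr$left, intr_ref, k1 = k1[1])
    fr$right <- undistort_pixels(fr$right, intr_ref, k1 = k1[2])
    fr
  })
  H_left <- lapply(undistorted, function(fr)
    homography_from_plane(obj_pts[, 1:2], fr$left))
  foc <- zhang_focal_fixed_pp(H_left, pp)
  ext <- lapply(H_left, function(H)
    extrinsics_from_homography(H, foc["fx"], foc["fy"], pp))
  # express every board pose in the frame-1 board frame (the world frame)
  R1 <- ext[[1]]$R; t1 <- ext[[1]]$t
  poses <- lapply(ext, function(e) {
    list(R = t(R1) %*% e$R, t = as.numeric(t(R1) %*% (e$t - t1)))
  })
  check_pose_diversity(poses)
  pxL <- do.call(rbind, lapply(undistorted, `[[`, "left"))
  pxR <- do.call(rbind, lapply(undistorted, `[[`, "right"))
  n_pts <- nrow(obj_pts)
  n_frames <- length(frames)
  rms_prev <- Inf
  best <- NULL
  for (sweep_i in seq_len(max_sweeps)) {
    world <- do.call(rbind, lapply(poses, apply_pose, pts = obj_pts))
    Lc <- dlt_solve(world, pxL)
    Rc <- dlt_solve(world, pxR)
    tri <- triangulate_many(pxL, pxR, Lc, Rc)$points
    poses <- lapply(seq_len(n_frames), function(i) {
      idx <- ((i - 1) * n_pts + 1):(i * n_pts)
      kabsch(obj_pts, tri[idx, , drop = FALSE])
    })
    posed <- do.call(rbind, lapply(poses, apply_pose, pts = obj_pts))
    rms <- sqrt(mean(rowSums((tri - posed)^2)))
    if (is.null(best) || rms < best$rms) {
      best <- list(left = Lc, right = Rc, poses = poses, rms = rms,
                   sweeps = sweep_i)
    }
    if (abs(rms_prev - rms) <= tol * max(rms_prev, 1e-12)) break
    rms_prev <- rms
  }
  best$focal_init <- foc
  best
}

check_pose_diversity <- function(poses) {
  t_mat <- do.call(rbind, lapply(poses, `[[`, "t"))
  spread_t <- max(apply(t_mat, 2, function(x) diff(range(x))))
  spread_R <- max(vapply(poses, function(p)
    max(abs(p$R - poses[[1]]$R)), numeric(1)))
  if (spread_t < 1e-6 && spread_R < 1e-9) {
    stop("degenerate geometry: all board poses are identical", call. = FALSE)
  }
  invisible(TRUE)
}

#' Calibrate a stereo pair from checkerboard frame pairs
#'
#' Estimates 11 DLT coefficients per camera from paired views of a planar
#' checkerboard of known geometry. Board poses are initialised in closed form
#' (plane homographies, focal recovery with the principal point fixed at the
#' image centre, per-frame extrinsics) and then refined by alternating a
#' linear DLT solve (given poses) with triangulation and a Procrustes pose
#' update (given the DLT), minimising the RMS 3D distance between
#' triangulated corners and the ideal board placed at the estimated poses.
#' The world frame of the resulting calibration is the frame-1 board frame;
#' all derived lengths are invariant to that choice.
#'
#' @param frames List of frame pairs; each element is a list with `left` and
#'   `right` n x 2 pixel matrices of the board's inner corners, row-major from
#'   the same board corner in both views (see [read_corner_table()]).
#' @param spec The [checkerboard_spec()] describing the board.
#' @param resolution Sensor resolution `(width, height)`, pixels; fixes the
#'   principal point used by the closed-form initialisation.
#' @param estimate_k1 If `TRUE`, a per-camera 1-D search for the first-order
#'   radial distortion coefficient is wrapped around the fit.
#' @param k1_range Search interval for `estimate_k1`.
#' @param max_sweeps,tol Alternation iteration cap and relative convergence
#'   tolerance on the reconstruction RMS.
#' @return An object of class `dlt_calibration`: `left_coeffs`,
#'   `right_coeffs` (11 each), `k1_left`, `k1_right`,
#'   `rms_reconstruction_mm`, `n_frames`, the board `poses`, the `spec`, and
#'   the distortion reference intrinsics used to (un)distort pixels.
#' @export
calibrate_stereo <- function(frames, spec = checkerboard_spec(),
                             resolution = c(1920, 1080),
                             estimate_k1 = FALSE, k1_range = c(-0.05, 0.05),
                             max_sweeps = 60, tol = 1e-8) {
  if (length(frames) < 2) {
    stop("insufficient frames: at least 2 checkerboard frame pairs are required",
         call. = FALSE)
  }
  obj_pts <- board_object_points(spec)
  n_pts <- nrow(obj_pts)
  for (fr in frames) {
    stopifnot(nrow(fr$left) == n_pts, nrow(fr$right) == n_pts,
              all(is.finite(fr$left)), all(is.finite(fr$right)))
  }
  base_fit <- fit_dlt_given_k1(frames, obj_pts, resolution,
                               max_sweeps = max_sweeps, tol = tol)
  k1 <- c(0, 0)
  intr_ref <- camera_intrinsics(resolution,
                                fx = base_fit$focal_init[["fx"]],
                                fy = base_fit$focal_init[["fy"]])
  fit <- base_fit
  if (estimate_k1) {
    for (cam_i in 1:2) {
      obj_fun <- function(k) {
        kk <- k1
        kk[cam_i] <- k
        fit_dlt_given_k1(frames, obj_pts, resolution, k1 = kk,
                         intr_ref = intr_ref, max_sweeps = 15, tol = 1e-6)$rms
      }
      k1[cam_i] <- stats::optimize(obj_fun, k1_range, tol = 1e-4)$minimum
    }
    fit <- fit_dlt_given_k1(frames, obj_pts, resolution, k1 = k1,
                            intr_ref = intr_ref,
                            max_sweeps = max_sweeps, tol = tol)
  }
  structure(list(
    left_coeffs = fit$left, right_coeffs = fit$right,
    k1_left = k1[1], k1_right = k1[2],
    rms_reconstruction_mm = fit$rms,
    n_frames = length(frames),
    sweeps = fit$sweeps,
    poses = fit$poses,
    spec = spec,
    resolution = as.numeric(resolution),
    distortion_ref = list(fx = intr_ref$fx, fy = intr_ref$fy,
                          principal_point = intr_ref$principal_point)
  ), class = "dlt_calibration")
}

#' @export
print.dlt_calibration <- function(x, ...) {
  cat(sprintf(
    "<dlt_calibration> %d frame pairs, reconstruction RMS %.4g mm, k1 = (%.4g, %.4g)\n",
    x$n_frames, x$rms_reconstruction_mm, x$k1_left, x$k1_right))
  invisible(x)
}

# undistort observed pixels using the calibration's distortion reference
cal_undistort <- function(px, cal, side) {
  k1 <- if (side == "left") cal$k1_left else cal$k1_right
  if (k1 == 0) return(rbind(px))
  ref <- cal$distortion_ref
  intr <- camera_intrinsics(cal$resolution, fx = ref$fx, fy = ref$fy,
                            principal_point = ref$principal_point)
  undistort_pixels(px, intr, k1 = k1)
}

#' Triangulate a paired pixel observation
#'
#' Solves the 4-equation, 3-unknown least-squares system formed by both
#' cameras' DLT relations for one matched pixel pair. Observed pixels are
#' undistorted with the calibration's per-camera `k1` before solving.
#'
#' @param left_px,right_px Length-2 pixel coordinates `(u, v)`.
#' @param cal A [calibrate_stereo()] result.
#' @return List with `point` (world coordinates, mm) and `rms` (RMS of the
#'   reprojected-vs-observed pixel residuals over both views).
#' @export
triangulate <- function(left_px, right_px, cal) {
  stopifnot(inherits(cal, "dlt_calibration"))
  pl <- cal_undistort(rbind(as.numeric(left_px)), cal, "left")
  pr <- cal_undistort(rbind(as.numeric(right_px)), cal, "right")
  Lc <- cal$left_coeffs; Rc <- cal$right_coeffs
  A <- rbind(
    c(Lc[1] - pl[1] * Lc[9], Lc[2] - pl[1] * Lc[10], Lc[3] - pl[1] * Lc[11]),
    c(Lc[5] - pl[2] * Lc[9], Lc[6] - pl[2] * Lc[10], Lc[7] - pl[2] * Lc[11]),
    c(Rc[1] - pr[1] * Rc[9], Rc[2] - pr[1] * Rc[10], Rc[3] - pr[1] * Rc[11]),
    c(Rc[5] - pr[2] * Rc[9], Rc[6] - pr[2] * Rc[10], Rc[7] - pr[2] * Rc[11]))
  b <- c(pl[1] - Lc[4], pl[2] - Lc[8], pr[1] - Rc[4], pr[2] - Rc[8])
  sv <- svd(A, nu = 0, nv = 0)$d
  if ((sv[1] / sv[3])^2 > 1e12) {
    stop("ill-conditioned triangulation: rays are near-parallel", call. = FALSE)
  }
  x <- qr.solve(A, b)
  rep_l <- dlt_project(x, Lc)
  rep_r <- dlt_project(x, Rc)
  rms <- sqrt(mean(c((rep_l - pl)^2, (rep_r - pr)^2)))
  list(point = as.numeric(x), rms = rms)
}
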