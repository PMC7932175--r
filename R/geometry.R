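#' Focal length in pixels from a field-of-view angle
#'
#' Converts a lens field of view along one image axis into the equivalent
#' pinhole focal length in pixels, `f = (res/2) / tan(fov/2)`.
#'
#' @param fov_deg Field of view along the axis, degrees; must lie in (0, 180).
#' @param axis_resolution_px Sensor resolution along the same axis, pixels.
#' @return Focal length in pixels.
#' @examples
#' focal_from_fov(90, 2000)   # 1000
#' focal_from_fov(64.6, 1920) # GoPro narrow FOV, horizontal axis
#' @export
focal_from_fov <- function(fov_deg, axis_resolution_px) {
  if (!is.finite(fov_deg) || fov_deg <= 0 || fov_deg >= 180) {
    stop("fov_deg must lie strictly between 0 and 180 degrees", call. = FALSE)
  }
  if (axis_resolution_px <= 0) {
    stop("axis_resolution_px must be positive", call. = FALSE)
  }
  (axis_resolution_px / 2) / tan(fov_deg * pi / 360)
}

#' Camera intrinsics
#'
#' A pinhole intrinsics description. When built from a pair of field-of-view
#' angles the per-axis focal lengths are derived with [focal_from_fov()]; the
#' horizontal and vertical FOV jointly determine `fx` and `fy`, which need not
#' be equal.
#'
#' @param resolution Integer pair `(width, height)` in pixels.
#' @param fov_h_deg,fov_v_deg Horizontal / vertical field of view, degrees.
#'   Either both FOVs or both focal lengths must be given.
#' @param fx,fy Focal lengths in pixels (override the FOV-derived values).
#' @param principal_point Pixel `(u0, v0)`; defaults to the image centre.
#' @param k1 First-order radial distortion coefficient (dimensionless, radius
#'   normalised by focal length). Defaults to 0.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(resolution = c(1920, 1080),
                              fov_h_deg = NULL, fov_v_deg = NULL,
                              fx = NULL, fy = NULL,
                              principal_point = resolution / 2,
                              k1 = 0) {
  stopifnot(length(resolution) == 2, all(resolution > 0))
  if (is.null(fx)) {
    if (is.null(fov_h_deg)) stop("supply either fov_h_deg or fx", call. = FALSE)
    fx <- focal_from_fov(fov_h_deg, resolution[1])
  }
  if (is.null(fy)) {
    fy <- if (is.null(fov_v_deg)) fx else focal_from_fov(fov_v_deg, resolution[2])
  }
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive", call. = FALSE)
  pp <- as.numeric(principal_point)
  if (pp[1] < 0 || pp[1] > resolution[1] || pp[2] < 0 || pp[2] > resolution[2]) {
    stop("principal_point must lie within the sensor", call. = FALSE)
  }
  structure(
    list(fx = fx, fy = fy, resolution = as.numeric(resolution),
         principal_point = pp, k1 = k1,
         fov_h_deg = if (is.null(fov_h_deg)) 2 * atan(resolution[1] / (2 * fx)) * 180 / pi else fov_h_deg,
         fov_v_deg = if (is.null(fov_v_deg)) 2 * atan(resolution[2] / (2 * fy)) * 180 / pi else fov_v_deg),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> %dx%d px, fx=%.1f fy=%.1f px, FOV %.1fx%.1f deg, k1=%g\n",
              x$resolution[1], x$resolution[2], x$fx, x$fy,
              x$fov_h_deg, x$fov_v_deg, x$k1))
  invisible(x)
}

#' Rotation matrix from yaw/pitch/roll
#'
#' World axes are +x starboard (toward the right camera), +y down, +z forward
#' (away from the vehicle toward targets). The matrix columns are the camera's
#' right/down/forward axes expressed in the world frame,
#' `R = Ry(yaw) %*% Rx(pitch) %*% Rz(roll)`. Positive yaw swings the optical
#' axis toward +x, so a left camera (mounted at negative x) with positive yaw
#' is toed in toward the rig midline.
#'
#' @param yaw_deg,pitch_deg,roll_deg Rotation angles in degrees.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @export
rotation_ypr <- function(yaw_deg = 0, pitch_deg = 0, roll_deg = 0) {
  a <- yaw_deg * pi / 180
  b <- pitch_deg * pi / 180
  g <- roll_deg * pi / 180
  Ry <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(b), sin(b), 0, -sin(b), cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Ry %*% Rx %*% Rz
}

#' Camera pose in the world frame
#'
#' @param position Numeric 3-vector, camera centre in world coordinates (mm).
#' @param yaw_deg,pitch_deg,roll_deg Orientation angles in degrees (see
#'   [rotation_ypr()] for the sign conventions).
#' @return An object of class `camera_pose` carrying the composed rotation.
#' @export
camera_pose <- function(position = c(0, 0, 0), yaw_deg = 0,
                        pitch_deg = 0, roll_deg = 0) {
  stopifnot(length(position) == 3, all(is.finite(position)),
            is.finite(yaw_deg), is.finite(pitch_deg), is.finite(roll_deg))
  R <- rotation_ypr(yaw_deg, pitch_deg, roll_deg)
  stopifnot(abs(det(R) - 1) < 1e-9)
  structure(list(position = as.numeric(position), yaw_deg = yaw_deg,
                 pitch_deg = pitch_deg, roll_deg = roll_deg, R = R),
            class = "camera_pose")
}

#' A camera: intrinsics plus pose
#' @param intrinsics A [camera_intrinsics()] object.
#' @param pose A [camera_pose()] object.
#' @return An object of class `rov_camera`.
#' @export
rov_camera <- function(intrinsics, pose) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"), inherits(pose, "camera_pose"))
  structure(list(intrinsics = intrinsics, pose = pose), class = "rov_camera")
}

#' @export
print.rov_camera <- function(x, ...) {
  cat(sprintf("<rov_camera> at (%.0f, %.0f, %.0f) mm, yaw %.1f deg\n",
              x$pose$position[1], x$pose$position[2], x$pose$position[3],
              x$pose$yaw_deg))
  print(x$intrinsics)
  invisible(x)
}

# radial distortion on normalised image coordinates: r' = r (1 + k1 r^2)
distort_normalized <- function(xn, yn, k1) {
  if (k1 == 0) return(cbind(xn, yn))
  s <- 1 + k1 * (xn^2 + yn^2)
  cbind(xn * s, yn * s)
}

# inverse of distort_normalized by Newton iteration on the radius
undistort_normalized <- function(xd, yd, k1) {
  if (k1 == 0) return(cbind(xd, yd))
  rd <- sqrt(xd^2 + yd^2)
  r <- rd
  for (i in 1:12) {
    f <- r * (1 + k1 * r^2) - rd
    fp <- 1 + 3 * k1 * r^2
    r <- r - f / fp
  }
  s <- ifelse(rd > 0, r / rd, 1)
  cbind(xd * s, yd * s)
}

#' Apply / remove first-order radial distortion in pixel coordinates
#'
#' Coordinates are normalised about a reference centre and focal length before
#' the radial model `r' = r (1 + k1 r^2)` is applied (or inverted by Newton
#' iteration).
#'
#' @param px n x 2 matrix of pixel coordinates.
#' @param intr A [camera_intrinsics()] object supplying the normalisation and
#'   `k1` (overridable).
#' @param k1 Distortion coefficient; defaults to `intr$k1`.
#' @return n x 2 matrix of distorted (or undistorted) pixels.
#' @export
distort_pixels <- function(px, intr, k1 = intr$k1) {
  px <- rbind(px)
  xn <- (px[, 1] - intr$principal_point[1]) / intr$fx
  yn <- (px[, 2] - intr$principal_point[2]) / intr$fy
  d <- distort_normalized(xn, yn, k1)
  cbind(d[, 1] * intr$fx + intr$principal_point[1],
        d[, 2] * intr$fy + intr$principal_point[2])
}

#' @rdname distort_pixels
#' @export
undistort_pixels <- function(px, intr, k1 = intr$k1) {
  px <- rbind(px)
  xn <- (px[, 1] - intr$principal_point[1]) / intr$fx
  yn <- (px[, 2] - intr$principal_point[2]) / intr$fy
  d <- undistort_normalized(xn, yn, k1)
  cbind(d[, 1] * intr$fx + intr$principal_point[1],
        d[, 2] * intr$fy + intr$principal_point[2])
}

#' Project world points into a camera
#'
#' Rigid transform to the camera frame, perspective division, first-order
#' radial distortion, then offset to pixel coordinates (origin top-left, u
#' right, v down). Projection is continuous; no quantisation is applied here.
#'
#' @param p Numeric 3-vector or n x 3 matrix of world points (mm).
#' @param camera A [rov_camera()] object.
#' @return A list with `px` (n x 2 pixels), `visible` (logical; inside the
#'   sensor and in front of the camera), `z_cam` (camera-frame depth, mm) and
#'   `behind` (logical). Points behind the camera are flagged, not errors;
#'   their pixel coordinates are `NA`.
#' @export
project_points <- function(p, camera) {
  p <- rbind(p)
  stopifnot(ncol(p) == 3)
  intr <- camera$intrinsics
  pose <- camera$pose
  rel <- sweep(p, 2, pose$position)
  pc <- rel %*% pose$R  # == t(R) %*% rel per point
  z <- pc[, 3]
  behind <- z <= 0
  xn <- pc[, 1] / z
  yn <- pc[, 2] / z
  d <- distort_normalized(xn, yn, intr$k1)
  u <- intr$principal_point[1] + intr$fx * d[, 1]
  v <- intr$principal_point[2] + intr$fy * d[, 2]
  u[behind] <- NA_real_
  v[behind] <- NA_real_
  visible <- !behind & u >= 0 & u < intr$resolution[1] &
    v >= 0 & v < intr$resolution[2]
  visible[is.na(visible)] <- FALSE
  list(px = cbind(u = u, v = v), visible = visible, z_cam = z, behind = behind)
}

# back-project a pixel to the camera-frame ray and intersect with plane z = z0
# (camera frame, k1 already removed); used by round-trip tests
back_project_to_depth <- function(px, camera, z0) {
  intr <- camera$intrinsics
  px <- rbind(px)
  xn <- (px[, 1] - intr$principal_point[1]) / intr$fx
  yn <- (px[, 2] - intr$principal_point[2]) / intr$fy
  pc <- cbind(xn * z0, yn * z0, z0)
  sweep(pc %*% t(camera$pose$R), 2, camera$pose$position, `+`)
}

#' Build the default pool stereo rig
#'
#' Two cameras symmetric about the rig midline at the given baseline, each
#' toed in toward the midline, plus a centre camera at the midline (0 deg
#' toe-in and tilt) carrying a parallel red-laser pair. Defaults follow the
#' pool rig: GoPro narrow FOV (64.6 x 49.1 deg) at 1920x1080, 10 deg toe-in,
#' baselines 406/610/762 mm and a 75 mm laser baseline.
#'
#' @param baseline_mm Stereo camera separation, mm.
#' @param toe_in_deg Inward rotation of each camera toward the midline, degrees.
#' @param fov_h_deg,fov_v_deg Field of view of every camera, degrees.
#' @param resolution Sensor resolution `(width, height)`, pixels.
#' @param k1 Radial distortion coefficient applied to all cameras.
#' @param laser_baseline_mm Separation of the parallel laser pair, mm.
#' @return An object of class `stereo_rig` with elements `left`, `right`,
#'   `center`, `baseline_mm`, `laser_baseline_mm`.
#' @export
default_pool_rig <- function(baseline_mm = 406, toe_in_deg = 10,
                             fov_h_deg = 64.6, fov_v_deg = 49.1,
                             resolution = c(1920, 1080), k1 = 0,
                             laser_baseline_mm = 75) {
  stopifnot(baseline_mm > 0, laser_baseline_mm > 0)
  intr <- camera_intrinsics(resolution, fov_h_deg, fov_v_deg, k1 = k1)
  rig <- structure(list(
    left = rov_camera(intr, camera_pose(c(-baseline_mm / 2, 0, 0), yaw_deg = +toe_in_deg)),
    right = rov_camera(intr, camera_pose(c(+baseline_mm / 2, 0, 0), yaw_deg = -toe_in_deg)),
    center = rov_camera(intr, camera_pose(c(0, 0, 0), yaw_deg = 0)),
    baseline_mm = baseline_mm,
    toe_in_deg = toe_in_deg,
    laser_baseline_mm = laser_baseline_mm
  ), class = "stereo_rig")
  stopifnot(abs(sqrt(sum((rig$left$pose$position - rig$right$pose$position)^2)) -
                  baseline_mm) < 1e-6)
  rig
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> baseline %.0f mm, toe-in %.1f deg, laser baseline %.0f mm\n",
              x$baseline_mm, x$toe_in_deg, x$laser_baseline_mm))
  invisible(x)
}
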