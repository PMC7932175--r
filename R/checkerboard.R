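#' Checkerboard specification
#'
#' Planar calibration target described by its inner-corner grid. The default
#' matches the pool-rig board: 7 x 5 inner corners, 63.7 mm squares.
#'
#' @param nx Inner corners per row (along the board's long axis).
#' @param ny Inner corners per column.
#' @param square_mm Square edge length, mm.
#' @return An object of class `checkerboard_spec`.
#' @export
checkerboard_spec <- function(nx = 7, ny = 5, square_mm = 63.7) {
  stopifnot(nx >= 2, ny >= 2, square_mm > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 square_mm = square_mm),
            class = "checkerboard_spec")
}

#' Ideal object points of a checkerboard
#'
#' Inner-corner coordinates in the board frame: a planar `nx x ny` grid on
#' z = 0, row-major from the board origin corner, spacing `square_mm`.
#'
#' @param spec A [checkerboard_spec()].
#' @return An `nx*ny` x 3 matrix of points (mm), row-major (x varies fastest).
#' @export
board_object_points <- function(spec = checkerboard_spec()) {
  stopifnot(inherits(spec, "checkerboard_spec"))
  g <- expand.grid(x = (seq_len(spec$nx) - 1) * spec$square_mm,
                   y = (seq_len(spec$ny) - 1) * spec$square_mm)
  cbind(x = g$x, y = g$y, z = 0)
}

# rigid board pose: rotation (yaw/pitch/roll, deg) + translation (mm)
board_pose <- function(translation, yaw_deg = 0, pitch_deg = 0, roll_deg = 0) {
  list(R = rotation_ypr(yaw_deg, pitch_deg, roll_deg),
       t = as.numeric(translation))
}

# apply a pose (list(R, t)) to an n x 3 point matrix
apply_pose <- function(pose, pts) {
  sweep(pts %*% t(pose$R), 2, pose$t, `+`)
}

# best-fit rigid transform (Kabsch) mapping X onto Y, both n x 3
kabsch <- function(X, Y) {
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(cy - R %*% cx))
}
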