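# Rigid-transform helpers shared by the forward and inverse kinematics.

#' Build a homogeneous transform from a rotation and a position
#'
#' A pose is represented throughout the package as a plain 4x4 matrix: a
#' 3x3 direction-cosine matrix in the upper-left block, a 3x1 position
#' (mm) in the fourth column, and an implicit bottom row `(0, 0, 0, 1)`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param position length-3 numeric, mm.
#' @param tol absolute tolerance for the orthonormality and determinant
#'   checks.  Use a looser tolerance (e.g. `1e-6`) for measured data.
#' @return 4x4 homogeneous transform matrix.
#' @export
new_pose <- function(rotation, position, tol = 1e-9) {
  if (!is.matrix(rotation) || !identical(dim(rotation), c(3L, 3L)) ||
      !all(is.finite(rotation))) {
    abort("`rotation` must be a finite 3x3 matrix.", class = "armkin_invalid_input")
  }
  if (length(position) != 3L || !all(is.finite(position))) {
    abort("`position` must be a finite 3-vector.", class = "armkin_invalid_input")
  }
  assert_rotation(rotation, tol = tol)
  rbind(cbind(rotation, as.numeric(position)), c(0, 0, 0, 1))
}

assert_rotation <- function(R, tol = 1e-9) {
  ortho <- max(abs(crossprod(R) - diag(3)))
  if (ortho > tol || abs(det(R) - 1) > tol) {
    abort(
      sprintf("rotation is not orthonormal with det +1 (residual %.3g, tol %.3g)",
              max(ortho, abs(det(R) - 1)), tol),
      class = c("armkin_invalid_pose", "armkin_invalid_input")
    )
  }
  invisible(R)
}

#' Extract the rotation block or position vector of a pose
#' @param pose 4x4 homogeneous transform.
#' @return 3x3 rotation matrix or length-3 position (mm).
#' @export
pose_rotation <- function(pose) pose[1:3, 1:3, drop = FALSE]

#' @rdname pose_rotation
#' @export
pose_position <- function(pose) pose[1:3, 4]

is_pose <- function(x) {
  is.matrix(x) && identical(dim(x), c(4L, 4L)) && all(is.finite(x))
}

#' Invert a rigid transform
#'
#' Uses the closed form `(R, p)^-1 = (R', -R'p)` rather than general matrix
#' inversion, for exactness and conditioning.
#'
#' @param pose 4x4 homogeneous transform.
#' @return 4x4 homogeneous transform.
#' @export
rigid_inverse <- function(pose) {
  R <- pose_rotation(pose)
  p <- pose_position(pose)
  rbind(cbind(t(R), -crossprod(R, p)), c(0, 0, 0, 1))
}

#' Geodesic distance between two rotations
#'
#' Rotation angle (rad) of `t(R1) %*% R2`, computed through the Frobenius
#' norm of the difference, `2 asin(||R1 - R2||_F / (2 sqrt(2)))`.  Unlike
#' the trace/acos form this stays accurate near zero, where acos loses
#' half the significant digits.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R1, R2) {
  2 * asin(min(1, frob_norm(R1 - R2) / (2 * sqrt(2))))
}

frob_norm <- function(M) sqrt(sum(M^2))

#' Pose residual used for branch selection
#'
#' Position error in mm plus the rotation geodesic angle in rad weighted by
#' 100 mm/rad, so a 0.01 rad orientation error counts like a 1 mm position
#' error.
#'
#' @param pose1,pose2 4x4 homogeneous transforms.
#' @return non-negative scalar.
#' @export
pose_distance <- function(pose1, pose2) {
  perr <- sqrt(sum((pose_position(pose1) - pose_position(pose2))^2))
  aerr <- rotation_angle(pose_rotation(pose1), pose_rotation(pose2))
  perr + 100 * aerr
}

#' Wrap angles into (-pi, pi]
#' @param x numeric vector of angles, rad.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y <= -pi, y + 2 * pi, y)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) abort("cannot normalise a zero vector.", class = "armkin_degenerate")
  v / n
}

deg2rad <- function(x) x * pi / 180

rad2deg <- function(x) x * 180 / pi
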