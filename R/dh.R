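# Denavit-Hartenberg parameterisation of the clavicle-shoulder-elbow-wrist
# chain and forward kinematics.
#
# Frame convention: origin at the sternoclavicular joint (point O), +X
# lateral toward the instrumented arm, +Z superior, +Y completing a
# right-handed frame.  Joints 1-2 orient the clavicle (the glenohumeral
# centre S sits at the tip of link l2), joints 3-5 form the shoulder ball
# joint with the upper-arm offset d5 ending at the elbow centre E, and
# joint 6 is elbow flexion with the forearm link l6 ending at the wrist
# centre EE (the end effector).

# twist angles of the six joints, fixed by the chain topology
DH_TWISTS <- c(-pi / 2, pi / 2, -pi / 2, pi / 2, -pi / 2, 0)

#' The Denavit-Hartenberg table of the arm chain
#'
#' Six rows, one per revolute joint, in the classic (distal) DH
#' convention: link angle `theta` (the joint variable), link offset `d`,
#' link length `l`, link twist `alpha`.  All offsets are zero except the
#' upper-arm offset `d5` on joint 5; all lengths are zero except the
#' clavicle `l2` on joint 2 and the forearm `l6` on joint 6.
#'
#' @param geometry an [arm_geometry()]; its link constants fill the
#'   symbolic `l2`, `d5`, `l6` entries.
#' @return a tibble with columns `joint`, `theta`, `d_mm`, `l_mm`,
#'   `alpha_rad`.
#' @examples
#' dh_table(arm_geometry())
#' @export
dh_table <- function(geometry = arm_geometry()) {
  geometry <- as_arm_geometry(geometry)
  tibble::tibble(
    joint = 1:6,
    theta = paste0("theta", 1:6),
    d_mm = c(0, 0, 0, 0, geometry$d5, 0),
    l_mm = c(0, geometry$l2, 0, 0, 0, geometry$l6),
    alpha_rad = DH_TWISTS
  )
}

#' Single-joint homogeneous transform from its DH row
#'
#' The classic DH matrix
#' \deqn{\begin{bmatrix}
#'   \cos\theta & -\sin\theta\cos\alpha &  \sin\theta\sin\alpha & l\cos\theta \\
#'   \sin\theta &  \cos\theta\cos\alpha & -\cos\theta\sin\alpha & l\sin\theta \\
#'   0 & \sin\alpha & \cos\alpha & d \\
#'   0 & 0 & 0 & 1
#' \end{bmatrix}}
#' with `d`, `l`, `alpha` taken from the joint's row of [dh_table()].
#'
#' @param joint joint index, 1-6.
#' @param theta joint angle, rad.
#' @param geometry an [arm_geometry()].
#' @return 4x4 homogeneous transform.
#' @export
dh_transform <- function(joint, theta, geometry = arm_geometry()) {
  geometry <- as_arm_geometry(geometry)
  if (!is.numeric(joint) || length(joint) != 1L || !joint %in% 1:6) {
    abort("`joint` must be a single integer in 1..6.", class = "armkin_invalid_input")
  }
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    abort("`theta` must be a single finite angle (rad).", class = "armkin_invalid_input")
  }
  d <- c(0, 0, 0, 0, geometry$d5, 0)[joint]
  l <- c(0, geometry$l2, 0, 0, 0, geometry$l6)[joint]
  a <- DH_TWISTS[joint]
  ct <- cos(theta); st <- sin(theta)
  ca <- cos(a); sa <- sin(a)
  # twists are multiples of pi/2: snap the cosines/sines so the printed
  # zero entries are exact zeros
  ca <- round(ca); sa <- round(sa)
  rbind(
    c(ct, -st * ca,  st * sa, l * ct),
    c(st,  ct * ca, -ct * sa, l * st),
    c(0,   sa,       ca,      d),
    c(0, 0, 0, 1)
  )
}

#' Forward kinematics of the six-joint arm chain
#'
#' Multiplies the six DH transforms cumulatively from the base.  The
#' position of `T02` is the glenohumeral (shoulder) centre S, the position
#' of `T05` is the elbow centre E, and the position of `T06` is the wrist
#' centre EE, the end effector.
#'
#' @param geometry an [arm_geometry()].
#' @param joints numeric length-6 vector of joint angles `theta1..theta6`,
#'   rad.
#' @return an object of class `arm_fk`: a list of the six cumulative
#'   transforms `T01..T06`, with the geometry and joint vector attached as
#'   attributes.
#' @examples
#' fk <- forward_kinematics(arm_geometry(), rep(0, 6))
#' fk_points(fk)
#' @export
forward_kinematics <- function(geometry, joints) {
  geometry <- as_arm_geometry(geometry)
  if (length(joints) != 6L || !all(is.finite(joints))) {
    abort("`joints` must be a finite length-6 angle vector (rad).",
          class = "armkin_invalid_input")
  }
  acc <- diag(4)
  out <- vector("list", 6L)
  for (j in 1:6) {
    acc <- acc %*% dh_transform(j, joints[[j]], geometry)
    out[[j]] <- acc
  }
  names(out) <- paste0("T0", 1:6)
  structure(out, class = "arm_fk", geometry = geometry, joints = as.numeric(joints))
}

#' Joint-centre positions of a forward-kinematics solution
#'
#' @param fk an `arm_fk` object from [forward_kinematics()].
#' @return tibble with columns `point` (O, S, E, EE), `x`, `y`, `z` (mm).
#' @export
fk_points <- function(fk) {
  stopifnot(inherits(fk, "arm_fk"))
  pts <- rbind(
    O  = c(0, 0, 0),
    S  = pose_position(fk$T02),
    E  = pose_position(fk$T05),
    EE = pose_position(fk$T06)
  )
  tibble::tibble(point = rownames(pts),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

#' @export
print.arm_fk <- function(x, ...) {
  th <- attr(x, "joints")
  cat("<arm_fk> joints (deg):", paste(sprintf("%.1f", rad2deg(th)), collapse = ", "), "\n")
  print(fk_points(x))
  invisible(x)
}

fk_pose <- function(geometry, joints) forward_kinematics(geometry, joints)$T06
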