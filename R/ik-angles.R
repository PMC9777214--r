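# Stage 2 of the inverse kinematics: closed-form extraction of the six
# joint angles from the end-effector pose plus the reconstructed shoulder
# and elbow centres.
#
# Each angle comes from an atan2 of two elements of a partial-chain
# matrix T0k^-1 * T06, peeled off joint by joint.  Three of the atan2
# pairs carry a pi-ambiguity (the roll/pitch/axial angles of the wrist
# triple): the raw value is correct only on one half-space of the
# neighbouring angle's sine or cosine.  Rather than assuming a posture,
# all branch combinations are enumerated and the candidate whose forward
# kinematics best reproduces the input pose is returned.

#' Clavicle angles from the shoulder position
#'
#' The shoulder centre in spherical coordinates on the clavicle sphere:
#' `Xc = l2 cos(theta2) cos(theta1)`, `Yc = l2 cos(theta2) sin(theta1)`,
#' `Zc = -l2 sin(theta2)`, whence
#' `theta1 = atan2(Yc, Xc)` and
#' `theta2 = atan2(-Zc, cos(theta1) Xc + sin(theta1) Yc)`.
#'
#' @param shoulder length-3 shoulder position, mm.
#' @param l2 clavicle length, mm (unused by the formulas themselves but
#'   kept for interface symmetry and the singularity scale).
#' @param eps singularity threshold on `sqrt(Xc^2 + Yc^2)`, mm.
#' @return named numeric `c(theta1, theta2)`, rad, each in `(-pi, pi]`.
#' @export
theta_1_2 <- function(shoulder, l2, eps = 1e-9) {
  if (sqrt(shoulder[1]^2 + shoulder[2]^2) <= eps * max(l2, 1)) {
    abort("shoulder lies on the base z-axis: theta1 is undefined (singular configuration).",
          class = "armkin_singular")
  }
  th1 <- atan2(shoulder[2], shoulder[1])
  th2 <- atan2(-shoulder[3], cos(th1) * shoulder[1] + sin(th1) * shoulder[2])
  c(theta1 = th1, theta2 = th2)
}

#' Shoulder roll angle
#'
#' From the partial chain T02^-1 * T06, comparing the first two rows of
#' the position column and of the rotation's first column:
#' `a = C1 C2 Px + C2 S1 Py - S2 Pz - l2`, `b = -S1 Px + C1 Py`,
#' `c = C1 C2 R11 + C2 S1 R21 - S2 R31`, `d = -S1 R11 + C1 R21`,
#' and `theta3 = atan2(b - l6 d, a - l6 c)`.
#'
#' Both atan2 arguments reduce to `d5 sin(theta4)` times the roll's
#' sine/cosine, so the raw value is exact when `sin(theta4) > 0` and off
#' by pi when `sin(theta4) < 0`; [solve_all()] resolves the branch.
#'
#' @param pose 4x4 end-effector pose.
#' @param theta1,theta2 clavicle angles, rad.
#' @param geometry an [arm_geometry()].
#' @param eps indeterminacy threshold on the atan2 argument pair, mm.
#' @return scalar `theta3`, rad.
#' @export
theta_3 <- function(pose, theta1, theta2, geometry, eps = 1e-9) {
  geometry <- as_arm_geometry(geometry)
  R <- pose_rotation(pose); P <- pose_position(pose)
  C1 <- cos(theta1); S1 <- sin(theta1)
  C2 <- cos(theta2); S2 <- sin(theta2)
  a <- C1 * C2 * P[1] + C2 * S1 * P[2] - S2 * P[3] - geometry$l2
  b <- -S1 * P[1] + C1 * P[2]
  cc <- C1 * C2 * R[1, 1] + C2 * S1 * R[2, 1] - S2 * R[3, 1]
  d <- -S1 * R[1, 1] + C1 * R[2, 1]
  y <- b - geometry$l6 * d
  x <- a - geometry$l6 * cc
  if (sqrt(x^2 + y^2) <= eps * max(geometry$d5, 1)) {
    abort("shoulder roll is indeterminate: both atan2 arguments vanish (sin(theta4) ~ 0).",
          class = "armkin_singular")
  }
  atan2(y, x)
}

#' Shoulder pitch angle
#'
#' From `M = T03^-1 * T06`, whose third rotation column is
#' `(-C4 S5, -S4 S5, C5)`: with `P = M[1,3]` and `Q = M[2,3]`,
#' `theta4 = atan2(Q, P)`.  The raw value equals `theta4` only where
#' `sin(theta5) < 0`; on the other half-space it is off by pi and is
#' resolved in [solve_all()].
#'
#' @param pose 4x4 end-effector pose.
#' @param theta1,theta2,theta3 preceding angles, rad.
#' @param geometry an [arm_geometry()].
#' @param eps singularity threshold on `|sin(theta5)| = sqrt(P^2 + Q^2)`.
#' @return scalar raw `theta4`, rad.
#' @export
theta_4 <- function(pose, theta1, theta2, theta3, geometry, eps = 1e-9) {
  geometry <- as_arm_geometry(geometry)
  T03 <- chain_to(geometry, c(theta1, theta2, theta3))
  M <- rigid_inverse(T03) %*% pose
  P <- M[1, 3]; Q <- M[2, 3]
  if (sqrt(P^2 + Q^2) <= eps) {
    abort("wrist singularity: sin(theta5) ~ 0, theta4 is indeterminate.",
          class = "armkin_singular")
  }
  atan2(Q, P)
}

#' Forearm axial-rotation angle
#'
#' From `M = T04^-1 * T06`, whose first rotation column is
#' `(C5 C6, S5 C6, -S6)`: `theta5 = atan2(M[2,1], M[1,1])`, i.e.
#' `atan2(S5 C6, C5 C6)`, exact where `cos(theta6) > 0` and off by pi
#' otherwise (resolved in [solve_all()]).
#'
#' @param pose 4x4 end-effector pose.
#' @param theta1,theta2,theta3,theta4 preceding angles, rad.
#' @param geometry an [arm_geometry()].
#' @param eps degeneracy threshold on `|cos(theta6)|`.
#' @return scalar raw `theta5`, rad.
#' @export
theta_5 <- function(pose, theta1, theta2, theta3, theta4, geometry, eps = 1e-9) {
  geometry <- as_arm_geometry(geometry)
  T04 <- chain_to(geometry, c(theta1, theta2, theta3, theta4))
  M <- rigid_inverse(T04) %*% pose
  if (sqrt(M[1, 1]^2 + M[2, 1]^2) <= eps) {
    abort("cos(theta6) ~ 0: the axial-rotation atan2 pair is degenerate.",
          class = "armkin_singular")
  }
  atan2(M[2, 1], M[1, 1])
}

#' Elbow flexion angle
#'
#' From `M = T05^-1 * T06 `, the last single-joint transform, whose first
#' rotation column is `(C6, S6, 0)`: `theta6 = atan2(M[2,1], M[1,1])`.
#' Exact; no branch ambiguity.
#'
#' @param pose 4x4 end-effector pose.
#' @param theta1,theta2,theta3,theta4,theta5 preceding angles, rad.
#' @param geometry an [arm_geometry()].
#' @return scalar `theta6`, rad.
#' @export
theta_6 <- function(pose, theta1, theta2, theta3, theta4, theta5, geometry) {
  geometry <- as_arm_geometry(geometry)
  T05 <- chain_to(geometry, c(theta1, theta2, theta3, theta4, theta5))
  M <- rigid_inverse(T05) %*% pose
  atan2(M[2, 1], M[1, 1])
}

# cumulative transform T0k for the first k angles
chain_to <- function(geometry, thetas) {
  acc <- diag(4)
  for (j in seq_along(thetas)) acc <- acc %*% dh_transform(j, thetas[[j]], geometry)
  acc
}

#' Full closed-form inverse kinematics of one end-effector pose
#'
#' Runs the position stage ([elbow_from_end_effector()],
#' [solve_shoulder_position()]) and then extracts `theta1..theta6`
#' sequentially.  The roll, pitch and axial angles each carry a
#' pi-ambiguity, so up to eight branch combinations are formed; each is
#' pushed through the forward kinematics and the candidate minimising the
#' pose residual (position error in mm plus rotation geodesic in rad,
#' weighted 100 mm/rad; see [pose_distance()]) is accepted.  Residual
#' ties (exact mirror solutions) are broken by closeness to `previous`
#' when given, otherwise by the smallest joint-vector norm.
#'
#' @param pose 4x4 end-effector pose.
#' @param geometry an [arm_geometry()].
#' @param previous optional length-6 joint vector of the previous frame;
#'   keeps both the shoulder-root choice and the wrist branch continuous
#'   along a trajectory.
#' @param shoulder_hint optional length-3 measured shoulder position (mm,
#'   base frame).  When the anatomical sign rules leave both geometric
#'   roots admissible, the root nearer the hint is selected; this is how
#'   the pipeline uses the shoulder marker cluster to resolve the
#'   algebraic ambiguity, including near plane-sphere tangency where the
#'   two roots approach each other.
#' @param mode `"strict"` errors on anatomical violations;
#'   `"streaming"` returns a flagged solution with `NaN` angles.
#' @param pose_tol accepted solutions must reproduce the pose to this
#'   residual; exceeding it raises an inconsistent-pose error.
#' @param rotation_tol orthonormality tolerance applied to the input pose.
#' @return an object of class `arm_ik`: a list with `joints` (named
#'   length-6, rad), `shoulder` (the `shoulder_solution`), `fk_residual`,
#'   `branch_flags`, and the inputs.  `tidy()` and `glance()` methods are
#'   available.
#' @examples
#' geom <- arm_geometry()
#' th <- c(0.3, -0.4, 0.5, 1.1, 0.6, 0.3)
#' sol <- solve_all(forward_kinematics(geom, th)$T06, geom)
#' max(abs(sol$joints - th)) < 1e-9
#' @export
solve_all <- function(pose, geometry, previous = NULL, shoulder_hint = NULL,
                      mode = c("strict", "streaming"),
                      pose_tol = 1e-6, rotation_tol = 1e-6) {
  mode <- match.arg(mode)
  geometry <- as_arm_geometry(geometry)
  if (!is_pose(pose)) {
    abort("`pose` must be a finite 4x4 homogeneous transform.",
          class = c("armkin_invalid_pose", "armkin_invalid_input"))
  }
  assert_rotation(pose_rotation(pose), tol = rotation_tol)

  elbow <- pose_position(pose) - geometry$l6 * pose[1:3, 1]
  prev_shoulder <- if (!is.null(shoulder_hint)) {
    as.numeric(shoulder_hint)
  } else if (!is.null(previous)) {
    pose_position(forward_kinematics(geometry, previous)$T02)
  }
  shoulder_sol <- solve_shoulder_position(pose, elbow, geometry, mode = mode,
                                          previous_shoulder = prev_shoulder)
  if (shoulder_sol$diagnostics$violation) {
    # streaming mode: NaN frame, carried by the pipeline
    return(structure(
      list(joints = setNames(rep(NaN, 6), paste0("theta", 1:6)),
           shoulder = shoulder_sol, fk_residual = NaN,
           branch_flags = NULL, pose = pose, geometry = geometry),
      class = "arm_ik"
    ))
  }

  S <- shoulder_sol$shoulder
  th12 <- theta_1_2(S, geometry$l2)
  th3_raw <- theta_3(pose, th12[1], th12[2], geometry)

  candidates <- list()
  flags <- list()
  for (flip3 in c(0, pi)) {
    th3 <- wrap_angle(th3_raw + flip3)
    th4_raw <- theta_4(pose, th12[1], th12[2], th3, geometry)
    for (flip4 in c(0, pi)) {
      th4 <- wrap_angle(th4_raw + flip4)
      th5_raw <- theta_5(pose, th12[1], th12[2], th3, th4, geometry)
      for (flip5 in c(0, pi)) {
        th5 <- wrap_angle(th5_raw + flip5)
        th6 <- theta_6(pose, th12[1], th12[2], th3, th4, th5, geometry)
        candidates[[length(candidates) + 1L]] <-
          c(th12[1], th12[2], th3, th4, th5, th6)
        flags[[length(flags) + 1L]] <-
          c(roll_flip = flip3 > 0, pitch_flip = flip4 > 0, axial_flip = flip5 > 0)
      }
    }
  }
  residuals <- vapply(candidates, function(th) {
    pose_distance(fk_pose(geometry, th), pose)
  }, numeric(1))

  near <- which(residuals <= min(residuals) + 1e-9)
  pick <- if (length(near) > 1L) {
    key <- if (!is.null(previous)) {
      vapply(near, function(i) sum(wrap_angle(candidates[[i]] - previous)^2), numeric(1))
    } else {
      vapply(near, function(i) sum(candidates[[i]]^2), numeric(1))
    }
    near[which.min(key)]
  } else {
    near[1]
  }

  if (residuals[pick] > pose_tol && mode == "strict") {
    abort(
      sprintf("no branch combination reproduces the pose (best residual %.3g > tolerance %.3g): inconsistent pose.",
              residuals[pick], pose_tol),
      class = "armkin_inconsistent_pose"
    )
  }

  structure(
    list(joints = setNames(candidates[[pick]], paste0("theta", 1:6)),
         shoulder = shoulder_sol,
         fk_residual = residuals[pick],
         branch_flags = flags[[pick]],
         n_candidates = length(candidates),
         pose = pose, geometry = geometry),
    class = "arm_ik"
  )
}

#' @export
print.arm_ik <- function(x, ...) {
  cat("<arm_ik>\n  joints (deg):",
      paste(sprintf("%.2f", rad2deg(x$joints)), collapse = ", "),
      sprintf("\n  fk residual: %.3g\n", x$fk_residual))
  invisible(x)
}

#' @describeIn solve_all tidy method: one row per joint with the angle in
#'   rad and deg.
#' @param x an `arm_ik` object.
#' @param ... unused.
#' @export
tidy.arm_ik <- function(x, ...) {
  tibble::tibble(
    joint = names(x$joints),
    angle_rad = as.numeric(x$joints),
    angle_deg = rad2deg(as.numeric(x$joints))
  )
}

#' @describeIn solve_all glance method: one-row solution summary.
#' @export
glance.arm_ik <- function(x, ...) {
  tibble::tibble(
    fk_residual = x$fk_residual,
    n_candidates = x$n_candidates %||% NA_integer_,
    ambiguous_root = isTRUE(x$shoulder$diagnostics$ambiguous),
    violation = isTRUE(x$shoulder$diagnostics$violation)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residuals of the intermediate closed-form identities
#'
#' Every intermediate identity used by the angle extraction can be checked
#' at the recovered angles: the orthogonality of the shoulder-elbow
#' segment to the end effector's z-axis, the shoulder sphere, the two
#' clavicle projections, the two elbow-column projections, the wrist
#' pitch column pair, the axial-rotation pair, and the flexion pair.
#' Position-type residuals are scaled by the relevant link length so every
#' entry is dimensionless and O(machine epsilon) on exact input.
#'
#' @param solution an `arm_ik` object from [solve_all()].
#' @return named numeric vector of twelve residuals.
#' @export
ik_identity_residuals <- function(solution) {
  stopifnot(inherits(solution, "arm_ik"))
  g <- solution$geometry
  pose <- solution$pose
  R <- pose_rotation(pose); P <- pose_position(pose)
  th <- solution$joints
  S <- solution$shoulder$shoulder
  E <- solution$shoulder$elbow
  C <- cos(th); Sn <- sin(th)

  a <- C[1] * C[2] * P[1] + C[2] * Sn[1] * P[2] - Sn[2] * P[3] - g$l2
  b <- -Sn[1] * P[1] + C[1] * P[2]
  cc <- C[1] * C[2] * R[1, 1] + C[2] * Sn[1] * R[2, 1] - Sn[2] * R[3, 1]
  d <- -Sn[1] * R[1, 1] + C[1] * R[2, 1]

  T03 <- chain_to(g, th[1:3]); M3 <- rigid_inverse(T03) %*% pose
  T04 <- chain_to(g, th[1:4]); M4 <- rigid_inverse(T04) %*% pose
  T05 <- chain_to(g, th[1:5]); M5 <- rigid_inverse(T05) %*% pose

  c(
    es_rz_orthogonality = sum((S - E) * R[, 3]) / g$l2,
    shoulder_sphere     = (sum(S^2) - g$l2^2) / g$l2^2,
    clavicle_inplane    = (C[1] * S[1] + Sn[1] * S[2] - g$l2 * C[2]) / g$l2,
    clavicle_vertical   = (-S[3] - g$l2 * Sn[2]) / g$l2,
    roll_scaled         = (g$l6 * C[6] * Sn[5] - (-a * Sn[3] + b * C[3])) / g$l6,
    roll_unit           = C[6] * Sn[5] - (-cc * Sn[3] + d * C[3]),
    pitch_cos           = M3[1, 3] + C[4] * Sn[5],
    pitch_sin           = M3[2, 3] + Sn[4] * Sn[5],
    axial_sin           = M4[2, 1] - Sn[5] * C[6],
    axial_cos           = M4[1, 1] - C[5] * C[6],
    flexion_cos         = M5[1, 1] - C[6],
    flexion_sin         = M5[2, 1] - Sn[6]
  )
}
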