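# Stage 1 of the inverse kinematics: reconstruct the elbow centre E and
# the shoulder (glenohumeral) centre S from a measured end-effector pose.
#
# The construction is purely geometric.  E lies a forearm length l6 behind
# the wrist along the end effector's x-axis.  S then satisfies three
# conditions simultaneously:
#   * it lies on the sphere of radius l2 about the base O (clavicle length),
#   * the segment E->S is perpendicular to the end effector's z-axis,
#   * the interior angle of the triangle O-S-E at E is fixed by the law of
#     cosines through the three link constants.
# The last two conditions are planes; their intersection line pierces the
# sphere in at most two points, giving a quadratic whose two roots are the
# two candidate shoulder positions.  Anatomy selects among them: in the
# normal state the clavicle points upward-oblique (Zc > 0) and the shoulder
# sits lateral to the sternoclavicular origin (Xc > 0).

#' Elbow centre from the end-effector pose
#'
#' The elbow lies one forearm length behind the wrist centre along the
#' end effector's x-axis: `E = P - l6 * R[, 1]`.
#'
#' @param pose 4x4 end-effector pose (see [new_pose()]).
#' @param l6 forearm length, mm (non-negative).
#' @param tol orthonormality tolerance for the pose rotation; measured
#'   poses warrant `1e-6`.
#' @return length-3 elbow position, mm.
#' @export
elbow_from_end_effector <- function(pose, l6, tol = 1e-6) {
  if (!is_pose(pose)) {
    abort("`pose` must be a finite 4x4 homogeneous transform.",
          class = c("armkin_invalid_pose", "armkin_invalid_input"))
  }
  if (!is.numeric(l6) || length(l6) != 1L || !is.finite(l6) || l6 < 0) {
    abort("`l6` must be a single non-negative length (mm).",
          class = "armkin_invalid_input")
  }
  assert_rotation(pose_rotation(pose), tol = tol)
  pose_position(pose) - l6 * pose[1:3, 1]
}

#' Interior angle of the O-S-E triangle at the elbow
#'
#' Law of cosines in the triangle formed by the base O, shoulder S and
#' elbow E, whose sides are `l2 = |OS|`, `d5 = |ES|` and the measured
#' `|OE|`:
#' `cos(theta0) = (d5^2 + |OE|^2 - l2^2) / (2 d5 |OE|)`.
#'
#' Also returns the plane constant `beta = |OE|^2 - d5 |OE| cos(theta0)`,
#' which reduces algebraically to `(|OE|^2 - d5^2 + l2^2) / 2` and is the
#' right-hand side of the linear constraint `E . S = beta` on the shoulder
#' position.
#'
#' @param elbow length-3 elbow position, mm.
#' @param geometry an [arm_geometry()].
#' @param tol tolerance by which `|cos(theta0)|` may exceed 1 before the
#'   target is declared unreachable (clamped when within tolerance).
#' @return list with elements `cos_theta0`, `beta`, `dist_oe`.
#' @export
cos_theta0 <- function(elbow, geometry, tol = 1e-9) {
  geometry <- as_arm_geometry(geometry)
  d_oe <- norm3(elbow)
  if (d_oe == 0) {
    abort("elbow coincides with the base: the triangle O-S-E is degenerate.",
          class = "armkin_degenerate")
  }
  c0 <- (geometry$d5^2 + d_oe^2 - geometry$l2^2) / (2 * geometry$d5 * d_oe)
  if (abs(c0) > 1 + tol) {
    abort(
      sprintf("elbow target at |OE| = %.2f mm is outside the reachability envelope (cos theta0 = %.6f)",
              d_oe, c0),
      class = "armkin_unreachable"
    )
  }
  c0 <- max(-1, min(1, c0))
  list(cos_theta0 = c0,
       beta = d_oe^2 - geometry$d5 * d_oe * c0,
       dist_oe = d_oe)
}

#' Derived plane coefficients for the shoulder solution
#'
#' The shoulder position C = (Xc, Yc, Zc) satisfies two linear equations:
#' the orthogonality plane `n . C = alpha` (with `n` the end effector's
#' z-axis and `alpha = n . E`) and the law-of-cosines plane `E . C = beta`.
#' Gaussian elimination of one coordinate from the pair yields two derived
#' planes in two unknowns each:
#' `p1 * C[b] + q1 * C[k] = r1` and `p2 * C[a] + q2 * C[k] = r2`,
#' where `(a, b, k)` is a permutation of the coordinates and `C[k]` is the
#' remaining quadratic variable.  In the default (well-conditioned) case
#' `(a, b, k) = (x, y, z)`: the first plane eliminates Xc using the pivot
#' `Xe`, the second eliminates Yc using `Ye`, and Zc is the quadratic
#' variable.  When a pivot `|E[a]|` or `|E[b]|` falls below
#' `eps = 1e-6 * l6` the elimination order is permuted so the two
#' largest-magnitude elbow coordinates are used as pivots.
#'
#' @param pose 4x4 end-effector pose.
#' @param elbow length-3 elbow position, mm.
#' @param alpha scalar: `n . E`, the orthogonality-plane constant.
#' @param beta scalar: the law-of-cosines plane constant, see
#'   [cos_theta0()].
#' @param eps pivot threshold, mm.
#' @return list with `plane1 = c(p1, q1, r1)`, `plane2 = c(p2, q2, r2)`,
#'   and `axes = c(a, b, k)`, the coordinate permutation used.
#' @export
shoulder_plane_coefficients <- function(pose, elbow, alpha, beta, eps = NULL) {
  n <- pose[1:3, 3]
  if (is.null(eps)) eps <- 1e-6 * max(norm3(elbow), 1)
  make_planes <- function(idx) {
    a <- idx[1]; b <- idx[2]; k <- idx[3]
    list(
      plane1 = c(p = n[b] - elbow[b] / elbow[a] * n[a],
                 q = n[k] - elbow[k] / elbow[a] * n[a],
                 r = alpha - n[a] / elbow[a] * beta),
      plane2 = c(p = n[a] - elbow[a] / elbow[b] * n[b],
                 q = n[k] - elbow[k] / elbow[b] * n[b],
                 r = alpha - n[b] / elbow[b] * beta),
      axes = idx
    )
  }
  # conditioning of the back-substitution: the two solved-for coefficients
  # must stay away from zero, else rounding in the quadratic is amplified
  score <- function(pl) min(abs(pl$plane1[["p"]]), abs(pl$plane2[["p"]]))
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L),
                c(2L, 1L, 3L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  valid <- Filter(function(idx) min(abs(elbow[idx[1:2]])) > eps, perms)
  if (!length(valid)) {
    abort("elbow position is too close to a coordinate axis: all elimination pivots vanish.",
          class = "armkin_degenerate")
  }
  # keep the default x/y-pivot, z-quadratic form whenever it is
  # comfortably conditioned; otherwise permute to the best-conditioned one
  default <- if (min(abs(elbow[1:2])) > eps) make_planes(c(1L, 2L, 3L))
  if (!is.null(default) && score(default) >= 0.05) return(default)
  cands <- lapply(valid, make_planes)
  best <- cands[[which.max(vapply(cands, score, numeric(1)))]]
  if (score(best) <= 1e-9) {
    abort("solution planes are degenerate for every elimination order.",
          class = "armkin_degenerate")
  }
  best
}

#' Solve for the shoulder centre from an end-effector pose
#'
#' Substituting the two derived planes of [shoulder_plane_coefficients()]
#' into the sphere equation `Xc^2 + Yc^2 + Zc^2 = l2^2` gives the quadratic
#' \deqn{(q_1^2/p_1^2 + q_2^2/p_2^2 + 1) Z_c^2
#'       - 2 (q_1 r_1/p_1^2 + q_2 r_2/p_2^2) Z_c
#'       + (r_1^2/p_1^2 + r_2^2/p_2^2) = l_2^2}
#' whose two roots are the two geometric shoulder candidates.  Candidates
#' are screened by the anatomical sign rules (clavicle upward-oblique,
#' `Zc > 0`; shoulder lateral to the sternoclavicular origin, `Xc > 0`).
#' If both candidates pass, the one with the larger `Zc` is selected,
#' unless `previous_shoulder` is supplied, in which case the candidate
#' closer to it is kept (root continuity along a trajectory).  If no
#' candidate passes, the configuration is an anatomical violation
#' ("shoulder dislocation"): an error in `strict` mode, a flagged
#' `NaN`-emitting solution in `streaming` mode.
#'
#' @param pose 4x4 end-effector pose.
#' @param elbow length-3 elbow position, mm (see
#'   [elbow_from_end_effector()]).
#' @param geometry an [arm_geometry()].
#' @param mode `"strict"` (errors on violation) or `"streaming"` (flags
#'   the frame and returns `NaN` coordinates).
#' @param previous_shoulder optional length-3 shoulder position of the
#'   previous frame, used to keep the root choice continuous.
#' @param disc_tol negative-discriminant magnitudes below
#'   `disc_tol * l2^2` are clamped to zero (tangency); larger ones raise
#'   an unreachable-target error.
#' @return an object of class `shoulder_solution`: a list with elements
#'   `shoulder`, `elbow`, `cos_theta0`, `alpha`, `beta`, `plane1`,
#'   `plane2`, `root_candidates` (the two Zc values), `candidates` (both
#'   full 3-vectors) and `diagnostics` (admissibility, ambiguity and
#'   violation flags, sphere and plane residuals).
#' @export
solve_shoulder_position <- function(pose, elbow, geometry,
                                    mode = c("strict", "streaming"),
                                    previous_shoulder = NULL,
                                    disc_tol = 1e-8) {
  mode <- match.arg(mode)
  geometry <- as_arm_geometry(geometry)
  ct <- cos_theta0(elbow, geometry)
  n <- pose[1:3, 3]
  alpha <- sum(n * elbow)
  planes <- shoulder_plane_coefficients(pose, elbow, alpha, ct$beta)

  # Solve the same elimination through the equivalent 2x2 linear system:
  # with k the quadratic coordinate and (a, b) the other two,
  # M (C[a], C[b])' = (alpha, beta)' - C[k] (n[k], e[k])', substituted into
  # the sphere.  Choosing k by the largest (row-normalised) minor of the
  # two plane normals keeps the back-substitution conditioned even when
  # the elbow sits near a coordinate axis, where the printed
  # divide-by-coordinate form loses digits.
  e_unit <- elbow / norm3(elbow)
  minors <- vapply(1:3, function(k) {
    ab <- setdiff(1:3, k)
    abs(n[ab[1]] * e_unit[ab[2]] - n[ab[2]] * e_unit[ab[1]])
  }, numeric(1))
  k <- which.max(minors)
  if (minors[k] <= 1e-9) {
    abort("solution planes are parallel: the shoulder position is degenerate.",
          class = "armkin_degenerate")
  }
  ab <- setdiff(1:3, k)
  a <- ab[1]; b <- ab[2]
  M <- rbind(n[ab], elbow[ab])
  u <- solve(M, c(alpha, ct$beta))
  v <- solve(M, c(n[k], elbow[k]))
  A <- 1 + sum(v^2)
  B <- -2 * sum(u * v)
  C <- sum(u^2) - geometry$l2^2
  disc <- B^2 - 4 * A * C
  clamped <- FALSE
  if (disc < 0) {
    if (disc > -disc_tol * geometry$l2^2) {
      disc <- 0
    } else if (mode == "streaming") {
      # a measured pose can fall epsilon outside the reachable set; the
      # nearest solution is the tangency point
      disc <- 0
      clamped <- TRUE
    } else {
      abort(
        sprintf("the plane intersection line misses the shoulder sphere (discriminant %.3g): unreachable pose.", disc),
        class = "armkin_unreachable"
      )
    }
  }
  roots_k <- c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
  candidates <- lapply(roots_k, function(K) {
    S <- numeric(3)
    S[k] <- K
    S[c(a, b)] <- u - K * v
    S
  })
  zc <- vapply(candidates, `[`, numeric(1), 3L)
  admissible <- vapply(candidates, function(S) S[3] > 0 && S[1] > 0, logical(1))

  diagnostics <- list(
    n_admissible = sum(admissible),
    ambiguous = sum(admissible) > 1L,
    violation = !any(admissible),
    clamped_discriminant = clamped,
    root_zc = zc
  )

  if (!any(admissible)) {
    if (mode == "strict") {
      abort(
        sprintf(paste0("anatomical violation (shoulder dislocation): neither shoulder ",
                       "candidate satisfies Zc > 0 and Xc > 0 (Zc = %.2f/%.2f, Xc = %.2f/%.2f)."),
                zc[1], zc[2], candidates[[1]][1], candidates[[2]][1]),
        class = "armkin_anatomical_violation"
      )
    }
    shoulder <- rep(NaN, 3)
  } else {
    ok <- which(admissible)
    pick <- if (length(ok) > 1L && !is.null(previous_shoulder) &&
                all(is.finite(previous_shoulder))) {
      ok[which.min(vapply(ok, function(i) sum((candidates[[i]] - previous_shoulder)^2),
                          numeric(1)))]
    } else {
      ok[which.max(zc[ok])]
    }
    shoulder <- candidates[[pick]]
    diagnostics$selected_root <- pick
    diagnostics$sphere_residual <- abs(sum(shoulder^2) - geometry$l2^2)
    diagnostics$plane_residuals <- c(
      orthogonality = sum(n * shoulder) - alpha,
      law_of_cosines = sum(elbow * shoulder) - ct$beta
    )
  }

  structure(
    list(shoulder = shoulder, elbow = elbow,
         cos_theta0 = ct$cos_theta0, alpha = alpha, beta = ct$beta,
         plane1 = planes$plane1, plane2 = planes$plane2,
         root_candidates = zc, candidates = candidates,
         diagnostics = diagnostics),
    class = "shoulder_solution"
  )
}

#' @export
print.shoulder_solution <- function(x, ...) {
  cat("<shoulder_solution>\n")
  cat(sprintf("  shoulder: (%.3f, %.3f, %.3f) mm\n",
              x$shoulder[1], x$shoulder[2], x$shoulder[3]))
  cat(sprintf("  elbow:    (%.3f, %.3f, %.3f) mm\n",
              x$elbow[1], x$elbow[2], x$elbow[3]))
  cat(sprintf("  root Zc candidates: %.3f, %.3f | admissible: %d | violation: %s\n",
              x$root_candidates[1], x$root_candidates[2],
              x$diagnostics$n_admissible, x$diagnostics$violation))
  invisible(x)
}
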