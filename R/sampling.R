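# Random joint-vector sampling restricted to the anatomically valid,
# branch-unambiguous domain.  Used by the validation suite and the
# acceptance script; the admissibility test is geometric (reflection of
# the shoulder across the plane-intersection line) and does not call the
# inverse-kinematics solver, so it can serve as an independent check on it.

#' Sample reachable, branch-valid joint vectors
#'
#' Rejection-samples joint vectors uniformly over a box and keeps those
#' whose forward kinematics satisfies the anatomical branch rules
#' (`Zc > 0`, `Xc > 0`), stays away from the extraction singularities
#' (`|sin(theta4)|`, `|sin(theta5)|`, `|cos(theta6)|` above
#' `singular_margin`), and - when `branch_valid` - is recoverable by the
#' stateless max-`Zc` root rule: the alternative geometric shoulder root
#' (the reflection of the true shoulder across the intersection line of
#' the two solution planes) must either violate the sign rules or lie
#' below the true root.
#'
#' @param n number of joint vectors.
#' @param geometry an [arm_geometry()].
#' @param branch_valid require stateless-rule recoverability (see above).
#' @param singular_margin lower bound on the wrist-singularity sines and
#'   cosine.
#' @param max_tries rejection-sampling cap.
#' @return tibble with columns `theta1..theta6` (rad), `n` rows.
#' @export
sample_reachable_joints <- function(n, geometry = arm_geometry(),
                                    branch_valid = TRUE,
                                    singular_margin = 0.05,
                                    max_tries = 1000 * n) {
  geometry <- as_arm_geometry(geometry)
  out <- matrix(NA_real_, nrow = n, ncol = 6)
  got <- 0L
  tries <- 0L
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    th <- c(runif(1, -1.4, 1.4), runif(1, -1.5, -0.02),
            runif(1, -pi, pi), runif(1, -pi, pi),
            runif(1, -pi, pi), runif(1, -pi, pi))
    if (abs(sin(th[4])) < singular_margin) next
    if (abs(sin(th[5])) < singular_margin) next
    if (abs(cos(th[6])) < singular_margin) next
    if (cos(th[1]) * cos(th[2]) <= 0.02) next  # Xc > 0 with margin
    if (branch_valid && !joints_branch_valid(th, geometry)) next
    got <- got + 1L
    out[got, ] <- th
  }
  if (got < n) {
    abort(sprintf("could not sample %d valid joint vectors in %d tries.", n, max_tries),
          class = "armkin_invalid_input")
  }
  tibble::as_tibble(as.data.frame(out)) |>
    setNames(paste0("theta", 1:6))
}

# TRUE when the stateless max-Zc rule recovers the configuration's own
# shoulder: the alternative root is computed by reflecting S across the
# intersection line of the orthogonality and law-of-cosines planes.
joints_branch_valid <- function(joints, geometry) {
  fk <- forward_kinematics(geometry, joints)
  S <- pose_position(fk$T02)
  if (S[3] <= 0 || S[1] <= 0) return(FALSE)
  R <- pose_rotation(fk$T06)
  E <- pose_position(fk$T05)
  u <- cross3(R[, 3], E)     # direction of the plane-intersection line
  uu <- sum(u^2)
  if (uu < (1e-6 * geometry$l2)^2) return(FALSE)
  S2 <- S - 2 * (sum(S * u) / uu) * u
  alt_admissible <- S2[3] > 0 && S2[1] > 0
  !alt_admissible || S2[3] < S[3]
}
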