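# Synthetic-motion generation: ground-truth joint-angle profiles for the
# two rehabilitation movements, and marker clouds placed on the forward
# model so the whole measurement pipeline can be exercised without
# captured data.

# default signed amplitudes (deg) follow the cohort-average ROM pattern of
# the two movements; offsets keep every sampled configuration on the
# anatomically valid branch (clavicle upward-oblique, shoulder lateral)
MOTION_DEFAULTS <- list(
  abduction_adduction = list(
    amplitude_deg = c(24, -15, 39, 129, 57, 23),
    offset_deg = c(5, -12, 0, 16, 20, 12)
  ),
  external_internal = list(
    amplitude_deg = c(4, -3, 8, 8, 109, 24),
    offset_deg = c(5, -12, 0, 16, 20, 12)
  )
)

# body-frame marker offsets (mm); shoulder triad centroid is exactly zero,
# elbow and wrist pairs are symmetric about their joint centre
MARKER_OFFSETS <- list(
  SH = list(frame = 2L, offsets = list(c(30, 0, 0),
                                       c(-15, 15 * sqrt(3), 0),
                                       c(-15, -15 * sqrt(3), 0))),
  EL = list(frame = 5L, offsets = list(c(0, 30, 0), c(0, -30, 0))),
  WR = list(frame = 6L, offsets = list(c(0, 20, 0), c(0, -20, 0)))
)

MARKER_LABELS <- c("SC", "SH1", "SH2", "SH3", "EL1", "EL2", "WR1", "WR2")

#' Specification of a synthetic rehabilitation movement
#'
#' Describes smooth periodic joint-angle profiles: each repetition is a
#' raised-cosine cycle (zero velocity at the cycle endpoints, matching a
#' physical repetition) of the given amplitude about the given offset.
#' Defaults emulate the two studied movements - abduction/adduction
#' (dominated by the shoulder pitch, with the clavicle co-rotating) and
#' external/internal rotation (dominated by the forearm axial angle) -
#' with amplitudes following the cohort-average ROM pattern and 10
#' repetitions per recording.
#'
#' @param motion `"abduction_adduction"` or `"external_internal"`.
#' @param n_reps number of repetitions (cycles), >= 1.
#' @param sample_rate sampling rate, Hz.
#' @param cycle_period duration of one repetition, s.
#' @param amplitude_deg signed per-joint cycle amplitudes, deg (length 6).
#' @param offset_deg per-joint rest offsets, deg (length 6).
#' @param amplitude_jitter_sd SD of the per-cycle, per-joint amplitude
#'   jitter, deg.
#' @param marker_noise_sd isotropic Gaussian marker noise SD, mm.
#' @param seed integer seed; all draws of a run descend from it.
#' @return a `motion_profile_spec` list.
#' @export
motion_profile_spec <- function(motion = c("abduction_adduction", "external_internal"),
                                n_reps = 10, sample_rate = 50, cycle_period = 2,
                                amplitude_deg = NULL, offset_deg = NULL,
                                amplitude_jitter_sd = 0, marker_noise_sd = 0,
                                seed = 1L) {
  motion <- match.arg(motion)
  defaults <- MOTION_DEFAULTS[[motion]]
  amplitude_deg <- amplitude_deg %||% defaults$amplitude_deg
  offset_deg <- offset_deg %||% defaults$offset_deg
  if (length(amplitude_deg) != 6L || length(offset_deg) != 6L) {
    abort("`amplitude_deg` and `offset_deg` must have length 6.",
          class = "armkin_invalid_input")
  }
  if (n_reps < 1 || sample_rate <= 0 || cycle_period <= 0 ||
      amplitude_jitter_sd < 0 || marker_noise_sd < 0) {
    abort("invalid motion spec: need n_reps >= 1, positive rates/periods, non-negative noise SDs.",
          class = "armkin_invalid_input")
  }
  structure(
    list(motion = motion, n_reps = as.integer(n_reps),
         sample_rate = sample_rate, cycle_period = cycle_period,
         amplitude_deg = amplitude_deg, offset_deg = offset_deg,
         amplitude_jitter_sd = amplitude_jitter_sd,
         marker_noise_sd = marker_noise_sd, seed = as.integer(seed)),
    class = "motion_profile_spec"
  )
}

#' Generate ground-truth joint-angle profiles
#'
#' Each joint follows `offset + A_c * (1 - cos(2 pi u)) / 2` within cycle
#' `c` (`u` the within-cycle phase), with the per-cycle amplitude `A_c`
#' drawn once per cycle and joint as
#' `amplitude + N(0, amplitude_jitter_sd)`.  Every sampled configuration
#' must satisfy the anatomical branch conditions `Zc > 0` and `Xc > 0`;
#' otherwise generation stops with an error naming the first violating
#' sample.
#'
#' @param spec a [motion_profile_spec()].
#' @param amplitude_matrix optional `n_reps` x 6 matrix of signed per-cycle
#'   amplitudes (deg) overriding the jittered draws (useful for
#'   ground-truth tests).
#' @param geometry an [arm_geometry()] (used for the branch check only).
#' @return tibble with columns `time` (s), `cycle`, `theta1..theta6`
#'   (rad); the spec is attached as attribute `"spec"`.
#' @export
generate_joint_profiles <- function(spec, amplitude_matrix = NULL,
                                    geometry = arm_geometry()) {
  stopifnot(inherits(spec, "motion_profile_spec"))
  geometry <- as_arm_geometry(geometry)
  n_per <- round(spec$sample_rate * spec$cycle_period)
  n <- n_per * spec$n_reps + 1L
  time <- (seq_len(n) - 1L) / spec$sample_rate
  cycle <- pmin(floor(time / spec$cycle_period), spec$n_reps - 1L) + 1L
  u <- (time %% spec$cycle_period) / spec$cycle_period
  u[n] <- 1  # close the last cycle
  if (is.null(amplitude_matrix)) {
    set.seed(spec$seed)
    jit <- if (spec$amplitude_jitter_sd > 0) {
      matrix(rnorm(spec$n_reps * 6, 0, spec$amplitude_jitter_sd), spec$n_reps, 6)
    } else {
      matrix(0, spec$n_reps, 6)
    }
    amplitude_matrix <- matrix(rep(spec$amplitude_deg, each = spec$n_reps),
                               spec$n_reps, 6) +
      jit * sign(matrix(rep(spec$amplitude_deg, each = spec$n_reps), spec$n_reps, 6))
  }
  if (!all(dim(amplitude_matrix) == c(spec$n_reps, 6))) {
    abort("`amplitude_matrix` must be n_reps x 6.", class = "armkin_invalid_input")
  }
  shape <- (1 - cos(2 * pi * u)) / 2
  theta <- sapply(1:6, function(k) {
    deg2rad(spec$offset_deg[k] + amplitude_matrix[cbind(cycle, k)] * shape)
  })
  # anatomical branch validity: Zc = -l2 sin(theta2) > 0, Xc = l2 C2 C1 > 0
  zc <- -geometry$l2 * sin(theta[, 2])
  xc <- geometry$l2 * cos(theta[, 2]) * cos(theta[, 1])
  bad <- which(zc <= 0 | xc <= 0)
  if (length(bad)) {
    abort(sprintf("profile violates the anatomical branch conditions at sample %d (t = %.3f s): Zc = %.2f, Xc = %.2f.",
                  bad[1], time[bad[1]], zc[bad[1]], xc[bad[1]]),
          class = "armkin_anatomical_violation")
  }
  out <- tibble::tibble(time = time, cycle = cycle)
  for (k in 1:6) out[[paste0("theta", k)]] <- theta[, k]
  attr(out, "spec") <- spec
  out
}

#' Synthesize labelled marker trajectories from joint profiles
#'
#' Runs the forward model per frame and places the eight markers: `SC` at
#' the base O; three shoulder markers at fixed clavicle-frame offsets
#' whose centroid is exactly the glenohumeral centre S; elbow and wrist
#' marker pairs symmetric about E and EE, riding rigidly on the upper-arm
#' and forearm frames.  Isotropic Gaussian noise of SD
#' `spec$marker_noise_sd` (mm) is added to every coordinate.  An optional
#' rigid world transform (`world_rotation`, `world_offset`) maps the
#' base-frame coordinates into a simulated laboratory frame, to exercise
#' the pipeline's calibration step; the default is the identity.
#'
#' @param truth joint-profile tibble from [generate_joint_profiles()].
#' @param geometry an [arm_geometry()].
#' @param spec the [motion_profile_spec()] (noise SD and seed).
#' @param world_rotation 3x3 rotation applied to all coordinates.
#' @param world_offset length-3 translation, mm.
#' @return wide marker tibble: `time`, then `<label>_x/_y/_z` for the
#'   eight labels.
#' @export
synthesize_markers <- function(truth, geometry, spec,
                               world_rotation = diag(3),
                               world_offset = c(0, 0, 0)) {
  geometry <- as_arm_geometry(geometry)
  stopifnot(inherits(spec, "motion_profile_spec"))
  th_cols <- paste0("theta", 1:6)
  thm <- as.matrix(truth[, th_cols])
  n <- nrow(thm)
  coords <- matrix(NA_real_, n, 24)
  for (i in seq_len(n)) {
    fk <- forward_kinematics(geometry, thm[i, ])
    S_pos <- lapply(MARKER_OFFSETS$SH$offsets, function(o) {
      pose_position(fk$T02) + pose_rotation(fk$T02) %*% o
    })
    E_pos <- lapply(MARKER_OFFSETS$EL$offsets, function(o) {
      pose_position(fk$T05) + pose_rotation(fk$T05) %*% o
    })
    W_pos <- lapply(MARKER_OFFSETS$WR$offsets, function(o) {
      pose_position(fk$T06) + pose_rotation(fk$T06) %*% o
    })
    pts <- c(list(c(0, 0, 0)), S_pos, E_pos, W_pos)
    coords[i, ] <- unlist(lapply(pts, function(p) {
      as.numeric(world_rotation %*% as.numeric(p) + world_offset)
    }))
  }
  if (spec$marker_noise_sd > 0) {
    set.seed(spec$seed + 1L)
    coords <- coords + rnorm(length(coords), 0, spec$marker_noise_sd)
  }
  out <- tibble::tibble(time = truth$time)
  cols <- as.vector(t(outer(MARKER_LABELS, c("x", "y", "z"), paste, sep = "_")))
  for (j in seq_along(cols)) out[[cols[j]]] <- coords[, j]
  out
}

#' One-call synthetic recording
#'
#' [generate_joint_profiles()] followed by [synthesize_markers()].
#'
#' @inheritParams synthesize_markers
#' @param spec a [motion_profile_spec()].
#' @param geometry an [arm_geometry()].
#' @return list with elements `truth` (joint profiles) and `markers`.
#' @export
simulate_motion <- function(spec, geometry = arm_geometry(),
                            world_rotation = diag(3), world_offset = c(0, 0, 0)) {
  truth <- generate_joint_profiles(spec, geometry = geometry)
  markers <- synthesize_markers(truth, geometry, spec,
                                world_rotation = world_rotation,
                                world_offset = world_offset)
  list(truth = truth, markers = markers)
}
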