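# End-to-end measurement pipeline: labelled marker series -> joint
# centres -> end-effector pose series -> joint-angle trajectories ->
# range of motion.

#' Read a wide motion-capture marker CSV
#'
#' Expects one `time` column (seconds) and one `<label>_x/_y/_z` triple
#' per marker (mm).  The canonical labels are `SC`, `SH1..SH3`, `EL1`,
#' `EL2`, `WR1`, `WR2`; exports using other labels can be mapped with
#' `label_map` (a named character vector, `c(export_label = "SC", ...)`).
#'
#' @param path CSV path.
#' @param label_map optional named character vector renaming marker
#'   labels.
#' @return marker tibble (`time` + 24 coordinate columns).
#' @export
read_marker_csv <- function(path, label_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("marker file not found: %s", path), class = "armkin_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(label_map)) {
    for (from in names(label_map)) {
      for (ax in c("x", "y", "z")) {
        old <- paste(from, ax, sep = "_")
        new <- paste(label_map[[from]], ax, sep = "_")
        if (old %in% names(df)) names(df)[names(df) == old] <- new
      }
    }
  }
  needed <- c("time", as.vector(t(outer(MARKER_LABELS, c("x", "y", "z"),
                                        paste, sep = "_"))))
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(sprintf("marker CSV is missing column(s): %s",
                  paste(head(missing, 6), collapse = ", ")),
          class = "armkin_io_error")
  }
  if (is.unsorted(df$time, strictly = TRUE)) {
    abort("`time` must be strictly increasing.", class = "armkin_invalid_input")
  }
  df[, needed]
}

#' Write a marker tibble as CSV
#' @param markers marker tibble (see [read_marker_csv()] for the dialect).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(markers, path) {
  readr::write_csv(markers, path)
  invisible(path)
}

#' Low-pass filter marker trajectories
#'
#' Zero-phase (forward-backward) Butterworth low-pass applied to every
#' coordinate column, the standard pre-treatment of optical marker data:
#' measurement noise is broadband while voluntary movement lives below a
#' few Hz, so a 6 Hz cutoff (the conventional choice for slow upper-limb
#' movement) attenuates noise without touching the motion content.  Edge
#' transients are avoided by mirror-padding each end before filtering.
#' Frames with missing coordinates split the series; each complete run is
#' filtered separately and short runs are left untouched.
#'
#' @param markers marker tibble (see [read_marker_csv()]).
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param order Butterworth order (applied twice, forward and backward).
#' @return filtered marker tibble.
#' @export
filter_markers <- function(markers, cutoff_hz = 6, order = 4) {
  dt <- diff(markers$time)
  rate <- 1 / stats::median(dt)
  if (cutoff_hz >= rate / 2) {
    abort(sprintf("cutoff %.3g Hz is not below the Nyquist rate %.3g Hz.",
                  cutoff_hz, rate / 2), class = "armkin_invalid_input")
  }
  out <- markers
  for (col in setdiff(names(markers), "time")) {
    out[[col]] <- lowpass_runs(markers[[col]], rate, cutoff_hz, order)
  }
  out
}

# zero-phase Butterworth low-pass applied to each complete (finite) run
# of a series; even (mirror) end reflection, exact for series that start
# and end at rest (zero velocity), absorbs the filter transient
lowpass_runs <- function(x, rate, cutoff_hz, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  pad <- ceiling(6 * rate / cutoff_hz)
  filt1 <- function(v) {
    n <- length(v)
    if (n <= 3 * pad) return(v)
    y <- signal::filtfilt(bf, c(v[(pad + 1):2], v, v[(n - 1):(n - pad)]))
    y[(pad + 1):(pad + n)]
  }
  ok <- is.finite(x)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    x[idx] <- filt1(x[idx])
  }
  x
}

#' Low-pass filter unwrapped joint-angle trajectories
#'
#' Zero-phase Butterworth low-pass on each unwrapped angle series, the
#' angle-domain counterpart of [filter_markers()].  Slow rehabilitation
#' movement has essentially all its angular content below ~1 Hz, so the
#' default 3 Hz cutoff leaves the motion untouched (a single-harmonic
#' repetition passes with relative error below 1e-6) while suppressing
#' frame-to-frame solver noise, including the short transients the
#' closed-form decomposition produces where its conditioning degrades.
#' Flagged (`NaN`) frames split the series; complete runs are filtered
#' separately.
#'
#' @param trajectory an `arm_trajectory` from [angles_over_time()].
#' @param cutoff_hz low-pass cutoff, Hz.
#' @param order Butterworth order.
#' @return the trajectory with filtered `theta1..theta6`.
#' @export
filter_angle_trajectory <- function(trajectory, cutoff_hz = 3, order = 4) {
  rate <- 1 / stats::median(diff(trajectory$time))
  if (cutoff_hz >= rate / 2) {
    abort(sprintf("cutoff %.3g Hz is not below the Nyquist rate %.3g Hz.",
                  cutoff_hz, rate / 2), class = "armkin_invalid_input")
  }
  for (k in 1:6) {
    col <- paste0("theta", k)
    trajectory[[col]] <- lowpass_runs(trajectory[[col]], rate, cutoff_hz, order)
  }
  trajectory
}

#' Estimate joint centres from the marker clusters
#'
#' The base O is the single sternoclavicular marker; the glenohumeral
#' centre S is the centroid of the three shoulder markers; the elbow E
#' and wrist EE centres are the midpoints of their marker pairs.  All
#' centres are then re-expressed in the base frame: a per-frame
#' translation puts O at the origin, and the orientation comes from a
#' calibration pose - over the first `calibration_window` seconds the
#' mean O->S direction is projected onto the horizontal plane to define
#' +X, the laboratory up axis is +Z, and +Y completes the right-handed
#' frame.  Frames with any missing marker coordinate are flagged as gaps
#' and emit `NaN` centres.
#'
#' @param markers marker tibble.
#' @param calibration_window seconds of data used for the orientation
#'   calibration (default 1 s; the recording is assumed near rest there).
#' @param normalize apply the base-frame normalization (default TRUE;
#'   disable for data already expressed in the base frame).
#' @return tibble `time`, `gap`, then `O_x..EE_z` (mm, base frame); the
#'   world-to-base rotation is attached as attribute
#'   `"base_rotation"`.
#' @export
estimate_joint_centers <- function(markers, calibration_window = 1,
                                   normalize = TRUE) {
  n <- nrow(markers)
  get3 <- function(label) {
    as.matrix(markers[, paste(label, c("x", "y", "z"), sep = "_")])
  }
  O <- get3("SC")
  S <- (get3("SH1") + get3("SH2") + get3("SH3")) / 3
  E <- (get3("EL1") + get3("EL2")) / 2
  EE <- (get3("WR1") + get3("WR2")) / 2
  gap <- !stats::complete.cases(cbind(O, S, E, EE))

  Rwb <- diag(3)
  if (normalize) {
    calib <- markers$time <= markers$time[1] + calibration_window & !gap
    if (!any(calib)) {
      abort("no complete frames inside the calibration window.",
            class = "armkin_invalid_input")
    }
    dir <- colMeans(S[calib, , drop = FALSE] - O[calib, , drop = FALSE])
    dir[3] <- 0  # horizontal projection; +Z is laboratory up
    if (norm3(dir) < 1e-6) {
      abort("calibration O->S direction is vertical: base-frame X is undefined.",
            class = "armkin_degenerate")
    }
    x_axis <- unit3(dir)
    z_axis <- c(0, 0, 1)
    y_axis <- cross3(z_axis, x_axis)
    Rwb <- cbind(x_axis, y_axis, z_axis)
  }
  to_base <- function(Pm) {
    out <- (Pm - O) %*% Rwb   # row-vectors times R == t(R) %*% column-vectors
    out[gap, ] <- NaN
    out
  }
  Ob <- O - O; Ob[gap, ] <- NaN
  Sb <- to_base(S); Eb <- to_base(E); EEb <- to_base(EE)
  out <- tibble::tibble(time = markers$time, gap = gap)
  add3 <- function(out, name, M) {
    out[[paste0(name, "_x")]] <- M[, 1]
    out[[paste0(name, "_y")]] <- M[, 2]
    out[[paste0(name, "_z")]] <- M[, 3]
    out
  }
  out <- add3(out, "O", Ob)
  out <- add3(out, "S", Sb)
  out <- add3(out, "E", Eb)
  out <- add3(out, "EE", EEb)
  attr(out, "base_rotation") <- Rwb
  out
}

#' Build end-effector poses from joint-centre series
#'
#' Per frame the end-effector frame is anchored at the wrist centre: its
#' x-axis is the unit forearm direction `unit(EE - E)` (so the elbow
#' reconstruction `E = P - l6 x` is exact by construction); its z-axis is
#' `unit(x cross (S - E))`, which enforces the orthogonality of the
#' shoulder-elbow segment to the z-axis by construction and matches the
#' forward model's end-effector frame on noise-free data; y completes
#' the right-handed frame.  Frames with collinear S, E, EE geometry are
#' flagged as degenerate.
#'
#' @param centers joint-centre tibble from [estimate_joint_centers()].
#' @param collinear_tol sine of the smallest accepted angle between the
#'   forearm and upper-arm directions.
#' @return tibble `time`, `flag` (`"ok"`, `"gap"` or `"degenerate"`) and
#'   a `pose` list-column of 4x4 matrices (`NULL` where flagged).
#' @export
build_end_effector_poses <- function(centers, collinear_tol = 1e-9) {
  n <- nrow(centers)
  poses <- vector("list", n)
  flag <- character(n)
  for (i in seq_len(n)) {
    if (isTRUE(centers$gap[i])) { flag[i] <- "gap"; next }
    S <- c(centers$S_x[i], centers$S_y[i], centers$S_z[i])
    E <- c(centers$E_x[i], centers$E_y[i], centers$E_z[i])
    EE <- c(centers$EE_x[i], centers$EE_y[i], centers$EE_z[i])
    fore <- EE - E
    if (norm3(fore) == 0) { flag[i] <- "degenerate"; next }
    x <- fore / norm3(fore)
    zraw <- cross3(x, S - E)
    if (norm3(zraw) <= collinear_tol * max(norm3(S - E), 1)) {
      flag[i] <- "degenerate"; next
    }
    z <- zraw / norm3(zraw)
    y <- cross3(z, x)
    poses[[i]] <- rbind(cbind(x, y, z, EE), c(0, 0, 0, 1))
    flag[i] <- "ok"
  }
  tibble::tibble(time = centers$time, flag = flag, pose = poses)
}

#' Joint-angle trajectories from an end-effector pose series
#'
#' Applies the closed-form inverse kinematics ([solve_all()]) frame by
#' frame in streaming mode, tracking the previous frame's solution so
#' both the shoulder-root choice and the wrist branch stay continuous.
#' Anatomical-violation and degenerate frames are carried as flagged
#' `NaN`s; each angle series is then unwrapped (multiples of 2 pi added
#' to minimise frame-to-frame jumps across valid frames).
#'
#' @param poses pose tibble from [build_end_effector_poses()].
#' @param geometry an [arm_geometry()].
#' @param shoulder_hints optional n x 3 matrix of measured shoulder
#'   positions (mm, base frame), one row per frame; when supplied, each
#'   frame's geometric root ambiguity is resolved toward the measured
#'   shoulder rather than by continuity alone.
#' @param max_flagged_fraction error out when more than this fraction of
#'   frames is unusable.
#' @return an `arm_trajectory` tibble: `time`, `theta1..theta6` (rad,
#'   unwrapped), `qc_flag`, `fk_residual`, `es_rz_residual` (the
#'   orthogonality diagnostic, dimensionless).
#' @export
angles_over_time <- function(poses, geometry, shoulder_hints = NULL,
                             max_flagged_fraction = 0.5) {
  geometry <- as_arm_geometry(geometry)
  n <- nrow(poses)
  theta <- matrix(NaN, n, 6)
  qc <- character(n)
  resid <- rep(NaN, n)
  ortho <- rep(NaN, n)
  prev <- NULL
  for (i in seq_len(n)) {
    if (poses$flag[i] != "ok") { qc[i] <- poses$flag[i]; next }
    hint <- if (!is.null(shoulder_hints) && all(is.finite(shoulder_hints[i, ]))) {
      shoulder_hints[i, ]
    }
    sol <- tryCatch(
      solve_all(poses$pose[[i]], geometry, previous = prev, shoulder_hint = hint,
                mode = "streaming"),
      armkin_unreachable = function(e) NULL,
      armkin_inconsistent_pose = function(e) NULL,
      armkin_singular = function(e) NULL
    )
    if (is.null(sol)) { qc[i] <- "unsolvable"; next }
    if (any(!is.finite(sol$joints))) { qc[i] <- "violation"; next }
    theta[i, ] <- sol$joints
    qc[i] <- "ok"
    resid[i] <- sol$fk_residual
    ortho[i] <- ik_identity_residuals(sol)[["es_rz_orthogonality"]]
    prev <- sol$joints
  }
  if (mean(qc != "ok") > max_flagged_fraction) {
    abort(sprintf("trajectory quality too low: %.0f%% of frames flagged.",
                  100 * mean(qc != "ok")),
          class = "armkin_trajectory_quality")
  }
  theta <- apply(theta, 2, unwrap_angles)
  out <- tibble::tibble(time = poses$time)
  for (k in 1:6) out[[paste0("theta", k)]] <- theta[, k]
  out$qc_flag <- qc
  out$fk_residual <- resid
  out$es_rz_residual <- ortho
  class(out) <- c("arm_trajectory", class(out))
  attr(out, "geometry") <- geometry
  out
}

#' Unwrap an angle series
#'
#' Adds multiples of 2 pi so consecutive valid samples never jump by more
#' than pi; `NaN` gaps are bridged using the nearest preceding valid
#' sample.
#'
#' @param x numeric vector of wrapped angles, rad (may contain `NaN`).
#' @return unwrapped series.
#' @export
unwrap_angles <- function(x) {
  valid <- which(is.finite(x))
  if (length(valid) < 2) return(x)
  v <- x[valid]
  d <- diff(v)
  d <- d - 2 * pi * round(d / (2 * pi))
  x[valid] <- v[1] + c(0, cumsum(d))
  x
}

#' Per-joint range of motion of a trajectory
#'
#' In `global` mode the ROM of each joint is `max - min` over all valid
#' frames.  In `per_cycle` mode (the default, matching a repeated
#' exercise protocol) the recording is first segmented into repetitions
#' at the rising zero crossings of the dominant joint's velocity (the
#' dominant joint being the one with the largest global ROM unless
#' given), and the ROM is the mean over cycles of the per-cycle
#' `max - min`.
#'
#' @param trajectory an `arm_trajectory` (or any tibble with `time` and
#'   `theta1..theta6` columns).
#' @param mode `"per_cycle"` or `"global"`.
#' @param dominant_joint optional joint index 1-6 used for segmentation.
#' @param min_cycle_fraction cycles shorter than this fraction of the
#'   median cycle length are discarded (guards against velocity-sign
#'   flicker under noise).
#' @param smooth_window odd moving-average window (samples) applied to
#'   the dominant series before segmentation.
#' @return an `arm_rom` tibble: `joint`, `rom_deg`; attributes `mode`,
#'   `n_cycles`, `dominant_joint`.
#' @export
compute_rom <- function(trajectory, mode = c("per_cycle", "global"),
                        dominant_joint = NULL, min_cycle_fraction = 0.5,
                        smooth_window = 5) {
  mode <- match.arg(mode)
  th_cols <- paste0("theta", 1:6)
  thm <- as.matrix(trajectory[, th_cols])
  valid <- stats::complete.cases(thm)
  if (sum(valid) < 2) {
    abort("need at least two valid frames to compute a ROM.",
          class = "armkin_invalid_input")
  }
  thm <- thm[valid, , drop = FALSE]
  global_rom <- rad2deg(apply(thm, 2, function(v) diff(range(v))))
  if (all(global_rom == 0)) mode_eff <- "global" else mode_eff <- mode

  n_cycles <- NA_integer_
  dom <- dominant_joint %||% which.max(global_rom)
  if (mode_eff == "per_cycle") {
    breaks <- segment_cycles(thm[, dom], min_cycle_fraction = min_cycle_fraction,
                             smooth_window = smooth_window)
    if (length(breaks) < 2) {
      rom <- global_rom
      n_cycles <- 1L
    } else {
      per <- vapply(seq_len(length(breaks) - 1), function(ci) {
        seg <- thm[breaks[ci]:breaks[ci + 1], , drop = FALSE]
        apply(seg, 2, function(v) diff(range(v)))
      }, numeric(6))
      rom <- rad2deg(rowMeans(per))
      n_cycles <- length(breaks) - 1L
    }
  } else {
    rom <- global_rom
  }
  out <- tibble::tibble(joint = th_cols, rom_deg = as.numeric(rom))
  class(out) <- c("arm_rom", class(out))
  attr(out, "mode") <- mode
  attr(out, "n_cycles") <- n_cycles
  attr(out, "dominant_joint") <- dom
  out
}

# indices of cycle boundaries (local minima of the smoothed series,
# including both endpoints)
segment_cycles <- function(x, min_cycle_fraction = 0.5, smooth_window = 5) {
  n <- length(x)
  if (smooth_window > 1 && n > smooth_window) {
    k <- smooth_window %/% 2
    xs <- stats::filter(x, rep(1 / smooth_window, smooth_window), sides = 2)
    xs[seq_len(k)] <- x[seq_len(k)]
    xs[(n - k + 1):n] <- x[(n - k + 1):n]
    x <- as.numeric(xs)
  }
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  minima <- which(diff(s) > 0) + 1L   # falling -> rising
  breaks <- unique(c(1L, minima, n))
  # merge segments much shorter than the median into a neighbour by
  # removing the interior break that bounds them
  repeat {
    lens <- diff(breaks)
    if (length(lens) < 2) break
    med <- stats::median(lens)
    bad <- which(lens < min_cycle_fraction * med)
    if (!length(bad)) break
    j <- bad[1]
    rm_idx <- if (j == length(lens)) j else j + 1L
    breaks <- breaks[-rm_idx]
  }
  breaks
}

# last-observation-carried-forward for the velocity sign (base R)
zoo_locf <- function(s) {
  idx <- cumsum(!is.na(s))
  filled <- c(NA, s[!is.na(s)])[idx + 1]
  filled[is.na(filled)] <- s[!is.na(s)][1]
  filled
}

#' Composite shoulder ROM of a movement
#'
#' Abduction/adduction is driven jointly by the clavicle's vertical
#' rotation and the shoulder pitch, so its composite ROM is
#' `theta2 + theta4`; external/internal rotation is carried by the
#' forearm axial angle, so its composite is `theta5` alone.
#'
#' @param rom an `arm_rom` tibble from [compute_rom()], or a named
#'   numeric vector with entries `theta1..theta6` (deg).
#' @param motion `"abduction_adduction"` or `"external_internal"`.
#' @return composite ROM, deg.
#' @export
composite_rom <- function(rom, motion = c("abduction_adduction", "external_internal")) {
  motion <- match.arg(motion)
  vals <- if (inherits(rom, "data.frame")) {
    setNames(rom$rom_deg, rom$joint)
  } else {
    rom
  }
  if (motion == "abduction_adduction") {
    unname(vals[["theta2"]] + vals[["theta4"]])
  } else {
    unname(vals[["theta5"]])
  }
}

#' @describeIn compute_rom tidy method (returns the tibble unchanged).
#' @param x an `arm_rom` object.
#' @param ... unused.
#' @export
tidy.arm_rom <- function(x, ...) tibble::as_tibble(x)

#' @describeIn compute_rom glance method: mode, cycle count, dominant
#'   joint.
#' @export
glance.arm_rom <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    n_cycles = attr(x, "n_cycles"),
    dominant_joint = attr(x, "dominant_joint")
  )
}

#' Write the per-frame QC log as JSON lines
#'
#' One JSON object per frame with the time stamp, QC flag and the two
#' numeric diagnostics.
#'
#' @param trajectory an `arm_trajectory` from [angles_over_time()].
#' @param path output path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_qc_log <- function(trajectory, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(trajectory))) {
    rec <- list(time = trajectory$time[i],
                qc_flag = trajectory$qc_flag[i],
                fk_residual = trajectory$fk_residual[i],
                es_rz_residual = trajectory$es_rz_residual[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                na = "null"), con)
  }
  invisible(path)
}

#' Full pipeline: markers to ROM
#'
#' Convenience wrapper chaining [estimate_joint_centers()],
#' [build_end_effector_poses()], [angles_over_time()] and
#' [compute_rom()].
#'
#' @param markers marker tibble.
#' @param geometry an [arm_geometry()].
#' @param rom_mode passed to [compute_rom()].
#' @param calibration_window,normalize passed to
#'   [estimate_joint_centers()].
#' @param marker_filter_hz low-pass cutoff for [filter_markers()];
#'   `NULL` disables filtering.
#' @param angle_filter_hz low-pass cutoff for
#'   [filter_angle_trajectory()]; `NULL` disables filtering.
#' @return list with `trajectory` (an `arm_trajectory`) and `rom` (an
#'   `arm_rom`).
#' @export
analyze_markers <- function(markers, geometry = arm_geometry(),
                            rom_mode = c("per_cycle", "global"),
                            calibration_window = 1, normalize = TRUE,
                            marker_filter_hz = 6, angle_filter_hz = 3) {
  rom_mode <- match.arg(rom_mode)
  if (!is.null(marker_filter_hz)) {
    markers <- filter_markers(markers, cutoff_hz = marker_filter_hz)
  }
  centers <- estimate_joint_centers(markers, calibration_window = calibration_window,
                                    normalize = normalize)
  poses <- build_end_effector_poses(centers)
  hints <- as.matrix(centers[, c("S_x", "S_y", "S_z")])
  traj <- angles_over_time(poses, geometry, shoulder_hints = hints)
  if (!is.null(angle_filter_hz)) {
    traj <- filter_angle_trajectory(traj, cutoff_hz = angle_filter_hz)
  }
  rom <- compute_rom(traj, mode = rom_mode)
  list(trajectory = traj, rom = rom)
}
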