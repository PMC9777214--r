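# ggplot2 views of trajectories, ROM results and cohort tables.

#' Plot joint-angle trajectories
#'
#' One facet per joint, angle in degrees against time; flagged frames
#' appear as gaps.
#'
#' @param trajectory an `arm_trajectory` (or any tibble with `time` and
#'   `theta1..theta6`).
#' @param degrees plot in degrees (default) or radians.
#' @return a ggplot object.
#' @export
plot_angle_trajectory <- function(trajectory, degrees = TRUE) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(trajectory)[, c("time", paste0("theta", 1:6))],
    cols = dplyr::starts_with("theta"),
    names_to = "joint", values_to = "angle"
  )
  if (degrees) long$angle <- rad2deg(long$angle)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$angle)) +
    ggplot2::geom_line(colour = "#2c7fb8", na.rm = TRUE) +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "time (s)",
                  y = if (degrees) "joint angle (deg)" else "joint angle (rad)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.arm_trajectory <- function(object, ...) plot_angle_trajectory(object, ...)

#' Plot a per-joint ROM result
#'
#' @param rom an `arm_rom` from [compute_rom()].
#' @return a ggplot object.
#' @export
plot_rom <- function(rom) {
  ggplot2::ggplot(tibble::as_tibble(rom),
                  ggplot2::aes(x = .data$joint, y = .data$rom_deg)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "range of motion (deg)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.arm_rom <- function(object, ...) plot_rom(object)

#' Plot sex-stratified cohort means with SEM error bars
#'
#' @param cohort output of [cohort_stats()].
#' @param motion which motion to show (default: the first present).
#' @return a ggplot object.
#' @export
plot_cohort <- function(cohort, motion = NULL) {
  motion <- motion %||% cohort$motion[1]
  df <- cohort[cohort$motion == motion, , drop = FALSE]
  th_cols <- grep("^theta", names(df), value = TRUE)
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(th_cols),
                              names_to = "joint", values_to = "value")
  wide <- tidyr::pivot_wider(long[, c("stratum", "statistic", "joint", "value")],
                             names_from = "statistic", values_from = "value")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$joint, y = .data$mean,
                                     fill = .data$stratum)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "mean ROM (deg)", fill = "stratum",
                  title = motion) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
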