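# Run configuration: JSON/YAML loading with fail-closed validation.

RUN_CONFIG_DEFAULTS <- list(
  l2_mm = 180, d5_mm = 300, l6_mm = 260,
  motion = "abduction_adduction",
  rom_mode = "per_cycle",
  violation_policy = "streaming",
  pose_tol = 1e-6,
  calibration_window = 1,
  seed = 1L,
  n_reps = 10L,
  sample_rate = 50,
  cycle_period = 2,
  amplitude_jitter_sd = 0,
  marker_noise_sd = 0
)

read_config_file <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "armkin_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    abort(sprintf("unsupported config format '.%s' (use JSON or YAML).", ext),
          class = "armkin_config_error")
  )
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    abort("config file must contain a mapping of keys to values.",
          class = "armkin_config_error")
  }
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML file and merges it over the documented defaults.
#' Validation is fail-closed: unknown keys are an error, as are invalid
#' values (the error names the offending key).  An empty file yields the
#' full default configuration.
#'
#' @param path config path (`.json`, `.yml`, `.yaml`); `NULL` gives the
#'   defaults.
#' @return a validated named list of class `run_config` with elements
#'   `geometry` (an [arm_geometry()]) plus every key of the defaults.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else read_config_file(path)
  unknown <- setdiff(names(cfg), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "armkin_config_error")
  }
  merged <- modifyList(RUN_CONFIG_DEFAULTS, cfg)

  check_pos <- function(key) {
    v <- merged[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("config key \"%s\" must be a single positive number (got %s).",
                    key, paste(format(v), collapse = ", ")),
            class = "armkin_config_error")
    }
  }
  for (key in c("l2_mm", "d5_mm", "l6_mm", "pose_tol", "calibration_window",
                "sample_rate", "cycle_period")) check_pos(key)
  for (key in c("amplitude_jitter_sd", "marker_noise_sd")) {
    v <- merged[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("config key \"%s\" must be a single non-negative number.", key),
            class = "armkin_config_error")
    }
  }
  if (!merged$motion %in% c("abduction_adduction", "external_internal")) {
    abort("config key \"motion\" must be \"abduction_adduction\" or \"external_internal\".",
          class = "armkin_config_error")
  }
  if (!merged$rom_mode %in% c("per_cycle", "global")) {
    abort("config key \"rom_mode\" must be \"per_cycle\" or \"global\".",
          class = "armkin_config_error")
  }
  if (!merged$violation_policy %in% c("streaming", "strict")) {
    abort("config key \"violation_policy\" must be \"streaming\" or \"strict\".",
          class = "armkin_config_error")
  }
  if (merged$n_reps < 1) {
    abort("config key \"n_reps\" must be >= 1.", class = "armkin_config_error")
  }
  merged$seed <- as.integer(merged$seed)
  merged$geometry <- arm_geometry(merged$l2_mm, merged$d5_mm, merged$l6_mm)
  structure(merged, class = "run_config")
}
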