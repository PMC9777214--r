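#' Arm geometry: the three non-zero link constants of the chain
#'
#' The kinematic chain has exactly three non-zero link constants: the
#' clavicle length `l2` (sternoclavicular to glenohumeral joint), the
#' upper-arm offset `d5` (glenohumeral to humeroulnar joint) and the
#' forearm length `l6` (humeroulnar to distal radioulnar joint).  All are
#' in millimetres and must be strictly positive.
#'
#' The defaults (`l2` = 180, `d5` = 300, `l6` = 260 mm) are plausible adult
#' segment lengths; in practice the constants are measured per subject from
#' the joint-centre distances of a calibration recording (see
#' [link_length()]).
#'
#' @param l2_mm clavicle length, mm.
#' @param d5_mm upper-arm length, mm.
#' @param l6_mm forearm length, mm.
#' @return an object of class `arm_geometry`: a named list with elements
#'   `l2`, `d5`, `l6`.
#' @examples
#' geom <- arm_geometry(180, 300, 260)
#' @export
arm_geometry <- function(l2_mm = 180, d5_mm = 300, l6_mm = 260) {
  vals <- c(l2_mm = l2_mm, d5_mm = d5_mm, l6_mm = l6_mm)
  for (key in names(vals)) {
    v <- vals[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive finite number.", key),
            class = "armkin_invalid_input")
    }
  }
  structure(list(l2 = l2_mm, d5 = d5_mm, l6 = l6_mm), class = "arm_geometry")
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat(sprintf("<arm_geometry> l2 = %g mm, d5 = %g mm, l6 = %g mm\n",
              x$l2, x$d5, x$l6))
  invisible(x)
}

as_arm_geometry <- function(x) {
  if (inherits(x, "arm_geometry")) return(x)
  if (is.list(x) && all(c("l2_mm", "d5_mm", "l6_mm") %in% names(x))) {
    return(arm_geometry(x$l2_mm, x$d5_mm, x$l6_mm))
  }
  abort("cannot interpret `geometry`; pass arm_geometry() or a list with l2_mm, d5_mm, l6_mm.",
        class = "armkin_invalid_input")
}

#' Load arm geometry from a JSON or YAML config file
#'
#' The file must contain (at least) the keys `l2_mm`, `d5_mm`, `l6_mm`.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return an [arm_geometry()] object.
#' @export
read_arm_geometry <- function(path) {
  cfg <- read_config_file(path)
  missing <- setdiff(c("l2_mm", "d5_mm", "l6_mm"), names(cfg))
  if (length(missing)) {
    abort(sprintf("geometry config is missing key(s): %s",
                  paste(missing, collapse = ", ")),
          class = "armkin_config_error")
  }
  arm_geometry(cfg$l2_mm, cfg$d5_mm, cfg$l6_mm)
}

#' Euclidean distance between two 3-D points
#'
#' Used to derive the link constants from measured joint centres: each link
#' length is the distance between the two joint centres it connects.
#'
#' @param point_a,point_b length-3 numeric vectors, mm.
#' @return non-negative scalar distance, mm.
#' @examples
#' link_length(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
link_length <- function(point_a, point_b) {
  if (length(point_a) != 3L || length(point_b) != 3L ||
      !all(is.finite(point_a)) || !all(is.finite(point_b))) {
    abort("both points must be finite 3-vectors.", class = "armkin_invalid_input")
  }
  norm3(point_b - point_a)
}

#' Is an elbow target within the reachability envelope of the shoulder?
#'
#' A target elbow distance `|OE|` from the base admits a shoulder placement
#' only when the triangle inequality of the triangle O-S-E holds:
#' `||OE| - d5| <= l2 <= |OE| + d5`.
#'
#' @param dist_oe distance from base to elbow target, mm.
#' @param geometry an [arm_geometry()].
#' @return logical scalar.
#' @export
is_reachable_elbow <- function(dist_oe, geometry) {
  geometry <- as_arm_geometry(geometry)
  abs(dist_oe - geometry$d5) <= geometry$l2 &
    geometry$l2 <= dist_oe + geometry$d5
}
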