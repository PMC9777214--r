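# Sex-stratified cohort statistics of per-subject ROM records.

#' Round half away from zero
#'
#' The tables' reporting convention: one decimal, ties rounded away from
#' zero (unlike base R's banker's rounding).  Full precision is kept
#' internally; rounding happens only at reporting boundaries.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_out <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# population standard deviation (divisor n)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Cohort statistics of per-subject ROM records
#'
#' For each motion and each stratum (each sex plus the pooled cohort)
#' computes, per value column, the mean, the population standard
#' deviation (divisor `n` - the convention of the source tables, e.g.
#' five male heights 170, 174, 177, 190, 172 give SD 7.1) and the
#' standard error of the mean `SEM = SD / sqrt(n)`.
#'
#' @param records tibble of per-subject records with columns `subject_id`,
#'   `sex` (`"M"`/`"F"`), `motion`, and the `values` columns.
#' @param values character vector of numeric columns to summarise.
#' @return tibble with columns `motion`, `stratum` (`"M"`, `"F"`,
#'   `"all"`), `n`, `statistic` (`"mean"`, `"sd"`, `"sem"`) and the
#'   `values` columns, at full precision.
#' @examples
#' recs <- rom_table_fixtures("abduction_adduction")
#' cohort_stats(recs)
#' @export
cohort_stats <- function(records,
                         values = c("height_mm", paste0("theta", 1:6))) {
  missing <- setdiff(c("sex", "motion", values), names(records))
  if (length(missing)) {
    abort(sprintf("records are missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "armkin_invalid_input")
  }
  if (!nrow(records)) {
    abort("no records supplied.", class = "armkin_invalid_input")
  }
  strata <- function(df) {
    present <- intersect(c("M", "F"), unique(df$sex))
    out <- lapply(present, function(s) df[df$sex == s, , drop = FALSE])
    names(out) <- present
    c(out, list(all = df))
  }
  rows <- list()
  for (mo in unique(records$motion)) {
    df_m <- records[records$motion == mo, , drop = FALSE]
    for (stratum in names(strata(df_m))) {
      sub <- strata(df_m)[[stratum]]
      if (!nrow(sub)) {
        abort(sprintf("empty stratum '%s' for motion '%s'.", stratum, mo),
              class = "armkin_invalid_input")
      }
      for (stat in c("mean", "sd", "sem")) {
        fn <- switch(stat,
                     mean = mean,
                     sd = sd_pop,
                     sem = function(x) sd_pop(x) / sqrt(length(x)))
        vals <- vapply(values, function(v) fn(sub[[v]]), numeric(1))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          motion = mo, stratum = stratum, n = nrow(sub), statistic = stat,
          !!!as.list(vals)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Rounded reporting view of a cohort table
#'
#' Applies [round_half_out()] (1 decimal) to every value column, matching
#' the printed-table convention.
#'
#' @param cohort output of [cohort_stats()].
#' @param digits decimal places.
#' @return rounded cohort tibble.
#' @export
cohort_table_rounded <- function(cohort, digits = 1) {
  num_cols <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))], "n")
  dplyr::mutate(cohort, dplyr::across(dplyr::all_of(num_cols),
                                      ~ round_half_out(.x, digits)))
}

#' Composite ROM per stratum from a cohort table
#'
#' Computes the movement's composite ROM from the stratum mean rows of
#' the rounded reporting view: `theta2 + theta4` for
#' abduction/adduction, `theta5` for external/internal rotation.  The
#' rounded view is used because the composite is a reporting-level
#' quantity formed from the published one-decimal averages.
#'
#' @param records per-subject ROM records (see [cohort_stats()]).
#' @param motion which motion's composite to form.
#' @return tibble `stratum`, `composite_deg`.
#' @export
cohort_composites <- function(records,
                              motion = c("abduction_adduction", "external_internal")) {
  motion <- match.arg(motion)
  stats <- cohort_stats(records[records$motion == motion, , drop = FALSE])
  rounded <- cohort_table_rounded(stats)
  means <- rounded[rounded$statistic == "mean", , drop = FALSE]
  comp <- if (motion == "abduction_adduction") {
    means$theta2 + means$theta4
  } else {
    means$theta5
  }
  tibble::tibble(stratum = means$stratum, composite_deg = comp)
}

#' Bundled per-subject ROM records
#'
#' The per-subject, per-joint ROM values (deg) and subject heights (mm) of
#' the ten-subject study cohort (five males, five females), for the two
#' movements.  These are transcriptions of the published per-subject
#' rows; the cohort statistics derived from them reproduce the published
#' summary rows (with the documented exceptions noted in the package
#' vignette).
#'
#' @param motion `"abduction_adduction"`, `"external_internal"` or
#'   `"both"`.
#' @return tibble `subject_id`, `sex`, `height_mm`, `motion`,
#'   `theta1..theta6`.
#' @export
rom_table_fixtures <- function(motion = c("both", "abduction_adduction",
                                          "external_internal")) {
  motion <- match.arg(motion)
  files <- c(abduction_adduction = "rom_abduction_adduction.csv",
             external_internal = "rom_external_internal.csv")
  wanted <- if (motion == "both") names(files) else motion
  out <- lapply(wanted, function(mo) {
    path <- system.file("extdata", files[[mo]], package = "armkin", mustWork = TRUE)
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    df$motion <- mo
    df
  })
  dplyr::bind_rows(out)
}
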