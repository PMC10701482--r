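#' Construct a percent-change stability series
#'
#' A `qc_series` holds, for one analyte/material/level, the observed study
#' days and the percent change of each day's mean against the baseline mean
#' (`Xt% = 100 * (Xt - Xo) / Xo`). Series are usually built from raw
#' replicates with [build_series()]; this constructor also accepts
#' pre-computed percent changes (e.g. transcribed from a published table,
#' where raw replicates are not available).
#'
#' @param analyte,material,level identifying labels.
#' @param days integer study days with an observed mean (day 0 allowed for
#'   the baseline itself, where the percent change is 0 by construction).
#' @param pct_change percent changes parallel to `days`.
#' @param baseline_mean the baseline (day 0) triplicate mean `Xo`, when
#'   known; `NA` for series built from published percent changes.
#' @param daily_means optional named numeric of day means parallel to
#'   `days`.
#' @return A `qc_series` object.
#' @export
qc_series <- function(analyte, material, level, days, pct_change,
                      baseline_mean = NA_real_, daily_means = NULL) {
  days <- as.integer(days)
  pct_change <- as.numeric(pct_change)
  if (length(days) != length(pct_change))
    qc_abort("days and pct_change must have the same length",
             "qc_validation_error")
  if (anyNA(days) || any(days < 0L))
    qc_abort("days must be non-negative integers", "qc_validation_error")
  if (anyDuplicated(days))
    qc_abort("days must be unique", "qc_validation_error")
  if (anyNA(pct_change))
    qc_abort("pct_change must not contain NA; omit unobserved days instead",
             "qc_validation_error")
  if (!is.na(baseline_mean) && baseline_mean <= 0)
    qc_abort("baseline_mean must be positive", "qc_validation_error")
  o <- order(days)
  days <- days[o]; pct_change <- pct_change[o]
  if (!is.null(daily_means)) daily_means <- as.numeric(daily_means)[o]
  structure(
    list(analyte = as.character(analyte), material = as.character(material),
         level = as.character(level), days = days, pct_change = pct_change,
         baseline_mean = baseline_mean, daily_means = daily_means),
    class = "qc_series"
  )
}

#' @export
print.qc_series <- function(x, ...) {
  cat(sprintf("qc_series %s / %s / %s: %d observed day(s)\n",
              x$analyte, x$material, x$level, length(x$days)))
  if (length(x$days) > 0L) {
    show <- data.frame(day = x$days, pct_change = round(x$pct_change, 3))
    print(utils::head(show, 20L), row.names = FALSE)
  }
  invisible(x)
}

#' Build a stability series from raw replicate measurements
#'
#' Averages the non-missing replicates of each day; days on which every
#' replicate is missing are absent from the series (no imputation). The
#' baseline mean `Xo` is the mean of the non-missing day-0 replicates, and
#' `Xt% = 100 * (Xt - Xo) / Xo` for every observed study day.
#'
#' @param records a `qc_measurements` table covering exactly one
#'   analyte/material/level.
#' @return A `qc_series` (the baseline day 0 is included with
#'   `pct_change = 0`).
#' @export
#' @examples
#' m <- qc_measurements(data.frame(
#'   analyte = "AST", material = "MQ", level = "low",
#'   day = rep(0:1, each = 3), replicate = rep(1:3, 2),
#'   value = c(100, 100, 100, 103, 103, 103)
#' ))
#' build_series(m)$pct_change # 0 then 3
build_series <- function(records) {
  records <- qc_measurements(records)
  key <- unique(records[, c("analyte", "material", "level")])
  if (nrow(key) != 1L)
    qc_abort("records must cover exactly one analyte/material/level; see build_panel_series()",
             "qc_validation_error")
  obs <- records[!records$missing, , drop = FALSE]
  base <- obs$value[obs$day == 0L]
  if (length(base) == 0L)
    qc_abort(sprintf("no baseline (day 0) data for %s/%s/%s",
                     key$analyte, key$material, key$level),
             "qc_baseline_missing")
  xo <- mean(base)
  means <- tapply(obs$value, obs$day, mean)
  days <- as.integer(names(means))
  qc_series(key$analyte, key$material, key$level,
            days = days, pct_change = 100 * (as.numeric(means) - xo) / xo,
            baseline_mean = xo, daily_means = as.numeric(means))
}

#' Build stability series for every analyte/material/level in a dataset
#'
#' @param records a `qc_measurements` table.
#' @return A list of `qc_series`, one per analyte/material/level group, in
#'   first-appearance order.
#' @export
build_panel_series <- function(records) {
  records <- qc_measurements(records)
  key <- paste(records$analyte, records$material, records$level, sep = "\r")
  idx <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  lapply(idx, function(i) build_series(records[i, , drop = FALSE]))
}
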