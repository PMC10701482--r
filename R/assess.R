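#' Loss-of-stability decision rule
#'
#' A control level "qualifies" as unstable evidence when its exceedance
#' days (study days with `|Xt%| > TCL`) satisfy the rule. With
#' `consecutive = FALSE` (default) a level qualifies as soon as it collects
#' `min_days` exceedance days anywhere in the window, and its onset is its
#' earliest exceedance day; a single isolated exceedance never triggers
#' instability. With `consecutive = TRUE` the level needs a run of
#' `min_days` exceedances on consecutive calendar days (a missing day
#' breaks a run), and its onset is the first day of the earliest such run.
#' `decision_rule(min_days = 3, consecutive = TRUE)` is the literal
#' "more than two consecutive days" reading used in some study protocols.
#'
#' @param min_days minimum number of exceedance days (>= 1).
#' @param consecutive must the exceedances fall on consecutive days?
#' @return A `decision_rule` object.
#' @export
decision_rule <- function(min_days = 2L, consecutive = FALSE) {
  min_days <- as.integer(min_days)
  if (is.na(min_days) || min_days < 1L)
    qc_abort("min_days must be an integer >= 1", "qc_validation_error")
  structure(list(min_days = min_days, consecutive = isTRUE(consecutive)),
            class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(sprintf("decision_rule: >= %d exceedance day(s)%s\n", x$min_days,
              if (x$consecutive) ", consecutive" else ""))
  invisible(x)
}

#' Days on which a series exceeds its Total Change Limit
#'
#' Strict comparison on the absolute percent change: day `d` exceeds when
#' `|Xt%[d]| > TCL`. The baseline day 0 and unobserved (missing) days never
#' count.
#'
#' @param series a `qc_series`.
#' @param tcl a `tcl_spec` or a plain threshold in percent.
#' @return Increasing integer vector of exceedance days.
#' @export
exceedance_days <- function(series, tcl) {
  stopifnot(inherits(series, "qc_series"))
  if (inherits(tcl, "tcl_spec")) {
    if (!is.na(tcl$analyte) && tcl$analyte != series$analyte)
      qc_abort(sprintf("TCL is for analyte %s but series is %s",
                       tcl$analyte, series$analyte), "qc_validation_error")
    tcl <- tcl$tcl
  }
  keep <- series$days >= 1L & abs(series$pct_change) > tcl
  series$days[keep]
}

# onset day for one level's exceedance days under a rule, or NA
level_onset <- function(exc_days, rule) {
  if (length(exc_days) == 0L) return(NA_integer_)
  if (!rule$consecutive) {
    if (length(exc_days) >= rule$min_days) exc_days[1L] else NA_integer_
  } else {
    if (rule$min_days == 1L) return(exc_days[1L])
    runs <- split(exc_days, cumsum(c(1L, diff(exc_days) != 1L)))
    first <- vapply(runs[lengths(runs) >= rule$min_days], `[[`, 0L, 1L)
    if (length(first) > 0L) min(first) else NA_integer_
  }
}

#' Assess the stability of one analyte/material across its control levels
#'
#' Applies the decision rule to each level's exceedance days. If any level
#' qualifies, the analyte is declared unstable with onset day equal to the
#' smallest level onset, and the maximum permissible storage time is
#' `onset_day - 1`; otherwise it is stable through `study_end` (stability
#' beyond the observed window is unknown, not claimed). Levels with no
#' observed days at all are skipped, not errors (a level may be unusable
#' for one analyte).
#'
#' @param series_per_level a `qc_series` or list of them (the levels of one
#'   analyte/material).
#' @param tcl a `tcl_spec` or threshold in percent, shared by the levels.
#' @param rule a [decision_rule()].
#' @param study_end last study day of the material's window.
#' @return A `qc_verdict`: list with `analyte`, `material`, `stable`,
#'   `onset_day` (`NA` if stable), `max_storage_days`, `study_end`,
#'   `evidence` (per level, the ordered exceedance days), and
#'   `qualifying_levels`.
#' @export
assess_stability <- function(series_per_level, tcl, rule = decision_rule(),
                             study_end) {
  if (inherits(series_per_level, "qc_series"))
    series_per_level <- list(series_per_level)
  if (length(series_per_level) == 0L)
    qc_abort("no series supplied", "qc_no_data")
  series_per_level <- Filter(function(s) length(s$days) > 0L, series_per_level)
  if (length(series_per_level) == 0L)
    qc_abort("every supplied level is empty", "qc_no_data")
  an <- unique(vapply(series_per_level, `[[`, "", "analyte"))
  ma <- unique(vapply(series_per_level, `[[`, "", "material"))
  if (length(an) != 1L || length(ma) != 1L)
    qc_abort("levels must belong to one analyte/material",
             "qc_validation_error")
  study_end <- as.integer(study_end)

  evidence <- lapply(series_per_level, exceedance_days, tcl = tcl)
  names(evidence) <- vapply(series_per_level, `[[`, "", "level")
  onsets <- vapply(evidence, level_onset, 0L, rule = rule)
  qualifying <- names(onsets)[!is.na(onsets)]
  if (length(qualifying) > 0L) {
    onset <- min(onsets, na.rm = TRUE)
    verdict <- list(analyte = an, material = ma, stable = FALSE,
                    onset_day = onset, max_storage_days = onset - 1L,
                    study_end = study_end, evidence = evidence,
                    qualifying_levels = qualifying)
  } else {
    verdict <- list(analyte = an, material = ma, stable = TRUE,
                    onset_day = NA_integer_, max_storage_days = study_end,
                    study_end = study_end, evidence = evidence,
                    qualifying_levels = character(0))
  }
  structure(verdict, class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  if (x$stable) {
    cat(sprintf("%s (%s): stable through day %d\n",
                x$analyte, x$material, x$study_end))
  } else {
    cat(sprintf("%s (%s): UNSTABLE from day %d (max storage %d day(s))\n",
                x$analyte, x$material, x$onset_day, x$max_storage_days))
    for (lv in names(x$evidence))
      if (length(x$evidence[[lv]]) > 0L)
        cat(sprintf("  level %s exceedance days: %s\n", lv,
                    paste(x$evidence[[lv]], collapse = ", ")))
  }
  invisible(x)
}

# resolve tcl thresholds per (analyte, material).
# `tcls` is a data.frame with columns analyte, tcl and either material or
# matrix; with matrix, `matrix_map` translates materials (serum panels MQ,
# LI, LL; urine panel UC by default).
lookup_tcl <- function(tcls, analyte, material,
                       matrix_map = c(MQ = "serum", LI = "serum",
                                      LL = "serum", UC = "urine")) {
  if (!is.data.frame(tcls) || !all(c("analyte", "tcl") %in% names(tcls)))
    qc_abort("tcls must be a data.frame with columns analyte, tcl and material or matrix",
             "qc_config_error")
  if ("material" %in% names(tcls)) {
    hit <- tcls$tcl[tcls$analyte == analyte & tcls$material == material]
  } else if ("matrix" %in% names(tcls)) {
    mx <- matrix_map[[material]] %||% "serum"
    hit <- tcls$tcl[tcls$analyte == analyte & tcls$matrix == mx]
  } else {
    qc_abort("tcls needs a material or matrix column", "qc_config_error")
  }
  if (length(hit) == 0L) NA_real_ else hit[[1L]]
}

#' Assess a whole panel of stability series
#'
#' Groups the series by analyte/material, resolves each group's TCL, and
#' applies [assess_stability()] to every group.
#'
#' @param series list of `qc_series` covering the panel.
#' @param tcls threshold table: a data.frame with columns `analyte`, `tcl`
#'   and either `material` (direct per-material thresholds) or `matrix`
#'   (thresholds per serum/urine, translated via `matrix_map`, e.g. the
#'   output of [registry_tcls()]).
#' @param rule a [decision_rule()].
#' @param study_ends named integer vector of last study day per material.
#' @param matrix_map material-to-matrix translation used when `tcls` is
#'   keyed by matrix.
#' @return A data.frame classed `qc_verdicts` with one row per
#'   analyte/material (`analyte, material, stable, onset_day,
#'   max_storage_days, study_end, qualifying_levels, exceedance_days`), the
#'   full `qc_verdict` objects in `attr(, "verdicts")`.
#' @export
assess_panel <- function(series, tcls, rule = decision_rule(), study_ends,
                         matrix_map = c(MQ = "serum", LI = "serum",
                                        LL = "serum", UC = "urine")) {
  if (length(series) == 0L) {
    out <- data.frame(analyte = character(0), material = character(0),
                      stable = logical(0), onset_day = integer(0),
                      max_storage_days = integer(0), study_end = integer(0),
                      qualifying_levels = character(0),
                      exceedance_days = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("qc_verdicts", "data.frame")
    attr(out, "verdicts") <- list()
    return(out)
  }
  key <- vapply(series, function(s) paste(s$analyte, s$material, sep = "\r"),
                "")
  groups <- split(series, factor(key, levels = unique(key)))

  ids <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  missing_tcl <- character(0)
  tclv <- numeric(length(groups))
  for (i in seq_along(groups)) {
    tclv[i] <- lookup_tcl(tcls, ids[i, 1L], ids[i, 2L], matrix_map)
    if (is.na(tclv[i]))
      missing_tcl <- c(missing_tcl, sprintf("%s (%s)", ids[i, 1L], ids[i, 2L]))
  }
  if (length(missing_tcl) > 0L)
    qc_abort(paste0("no TCL resolvable for: ",
                    paste(missing_tcl, collapse = ", ")), "qc_config_error")

  ends <- study_ends[ids[, 2L]]
  if (anyNA(ends))
    qc_abort(paste0("study_ends lacks material(s): ",
                    paste(unique(ids[is.na(ends), 2L]), collapse = ", ")),
             "qc_config_error")

  verdicts <- vector("list", length(groups))
  for (i in seq_along(groups))
    verdicts[[i]] <- assess_stability(groups[[i]], tclv[i], rule, ends[i])

  out <- data.frame(
    analyte = vapply(verdicts, `[[`, "", "analyte"),
    material = vapply(verdicts, `[[`, "", "material"),
    stable = vapply(verdicts, `[[`, TRUE, "stable"),
    onset_day = vapply(verdicts, `[[`, 0L, "onset_day"),
    max_storage_days = vapply(verdicts, `[[`, 0L, "max_storage_days"),
    study_end = vapply(verdicts, `[[`, 0L, "study_end"),
    qualifying_levels = vapply(verdicts, function(v)
      paste(v$qualifying_levels, collapse = ";"), ""),
    exceedance_days = vapply(verdicts, function(v)
      paste(vapply(names(v$evidence), function(lv)
        paste0(lv, ":", paste(v$evidence[[lv]], collapse = " ")), ""),
        collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("qc_verdicts", "data.frame")
  attr(out, "verdicts") <- verdicts
  out
}

#' Stable/unstable counts for a verdict table
#'
#' @param verdicts a `qc_verdicts` data.frame from [assess_panel()].
#' @return list with `overall` (`stable`, `total`) and `by_material`
#'   data.frame.
#' @export
summarize_verdicts <- function(verdicts) {
  by_mat <- do.call(rbind, lapply(split(verdicts, verdicts$material), function(d)
    data.frame(material = d$material[1L], stable = sum(d$stable),
               total = nrow(d), stringsAsFactors = FALSE)))
  if (is.null(by_mat))
    by_mat <- data.frame(material = character(0), stable = integer(0),
                         total = integer(0), stringsAsFactors = FALSE)
  rownames(by_mat) <- NULL
  list(overall = c(stable = sum(verdicts$stable), total = nrow(verdicts)),
       by_material = by_mat)
}
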