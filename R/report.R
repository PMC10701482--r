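#' Render a day-by-day percent-change table
#'
#' Produces the familiar stability-report layout: one row per
#' analyte/level, day columns, then the TCL. Values are rounded for
#' display, exceedances (`|Xt%| > TCL`) carry a marker suffix, and
#' unobserved days render as an en dash.
#'
#' @param series list of `qc_series`.
#' @param tcls threshold table as in [assess_panel()] (columns `analyte`,
#'   `tcl`, plus `material` or `matrix`).
#' @param digits display rounding (the underlying series keep full
#'   precision).
#' @param mark suffix marking exceedance cells (`""` to disable).
#' @param missing string rendered for unobserved days.
#' @inheritParams assess_panel
#' @return A character data.frame `material, analyte, level, d1..dN, TCL`
#'   with a logical exceedance matrix in `attr(, "exceeded")`.
#' @export
render_change_table <- function(series, tcls, digits = 2, mark = "*",
                                missing = "–",
                                matrix_map = c(MQ = "serum", LI = "serum",
                                               LL = "serum", UC = "urine")) {
  if (length(series) == 0L) {
    out <- data.frame(material = character(0), analyte = character(0),
                      level = character(0), TCL = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "exceeded") <- matrix(FALSE, 0, 0)
    return(out)
  }
  max_day <- max(1L, unlist(lapply(series, function(s) s$days)))
  day_seq <- seq_len(max_day)
  rows <- vector("list", length(series))
  exceeded <- matrix(FALSE, length(series), max_day)
  for (i in seq_along(series)) {
    s <- series[[i]]
    tcl <- lookup_tcl(tcls, s$analyte, s$material, matrix_map)
    if (is.na(tcl))
      qc_abort(sprintf("no TCL resolvable for %s (%s)", s$analyte, s$material),
               "qc_config_error")
    cells <- rep(missing, max_day)
    idx <- match(day_seq, s$days)
    have <- !is.na(idx)
    val <- s$pct_change[idx[have]]
    exc <- abs(val) > tcl
    cells[have] <- paste0(as.character(round(val, digits)),
                          ifelse(exc, mark, ""))
    exceeded[i, have] <- exc
    rows[[i]] <- c(material = s$material, analyte = s$analyte,
                   level = s$level, setNames(cells, paste0("d", day_seq)),
                   TCL = as.character(round(tcl, digits)))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exceeded") <- exceeded
  out
}

#' Format a data.frame as a markdown pipe table
#'
#' @param x data.frame of displayable values.
#' @return A single character string of markdown.
#' @export
render_markdown <- function(x) {
  cells <- rbind(names(x), rep("---", ncol(x)),
                 as.matrix(format(x, justify = "left")))
  paste(apply(cells, 1L, function(r)
    paste0("| ", paste(trimws(r), collapse = " | "), " |")),
    collapse = "\n")
}

#' Plain-text summary of a stability verdict table
#'
#' @param verdicts a `qc_verdicts` data.frame from [assess_panel()].
#' @return Character vector of summary lines: overall and per-material
#'   stable counts, then each unstable analyte with its onset and maximum
#'   permissible storage time.
#' @export
#' @examples
#' cat(render_summary(reproduce_study()), sep = "\n")
render_summary <- function(verdicts) {
  s <- summarize_verdicts(verdicts)
  lines <- sprintf("%d of %d analyte/material combinations stable through their study windows",
                   s$overall[["stable"]], s$overall[["total"]])
  for (i in seq_len(nrow(s$by_material)))
    lines <- c(lines, sprintf("  %s: %d of %d stable",
                              s$by_material$material[i],
                              s$by_material$stable[i],
                              s$by_material$total[i]))
  unst <- verdicts[!verdicts$stable, , drop = FALSE]
  if (nrow(unst) == 0L) {
    lines <- c(lines, "no unstable analytes")
  } else {
    lines <- c(lines, "unstable:")
    for (i in seq_len(nrow(unst)))
      lines <- c(lines, sprintf(
        "  %s (%s): loss of stability at day %d, maximum storage %d day(s)",
        unst$analyte[i], unst$material[i], unst$onset_day[i],
        unst$max_storage_days[i]))
  }
  lines
}

#' Plot percent-change series with TCL bands
#'
#' Line plot of `Xt%` against day for each control level, with horizontal
#' lines at the positive and negative TCL. Unobserved days leave gaps in
#' the trace (no interpolation across missing data).
#'
#' @param series a `qc_series` or list of them (the levels of one
#'   analyte/material).
#' @param tcl a `tcl_spec` or a threshold in percent.
#' @param path optional PNG output path; when `NULL`, draws on the current
#'   device.
#' @param width,height device size in pixels when `path` is given.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_series <- function(series, tcl, path = NULL, width = 800, height = 500) {
  if (inherits(series, "qc_series")) series <- list(series)
  series <- Filter(function(s) length(s$days) > 0L, series)
  if (length(series) == 0L) qc_abort("no data to plot", "qc_no_data")
  if (inherits(tcl, "tcl_spec")) tcl <- tcl$tcl
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  max_day <- max(unlist(lapply(series, function(s) s$days)))
  day_seq <- seq_len(max_day)
  ymat <- vapply(series, function(s) {
    y <- rep(NA_real_, max_day)
    keep <- s$days >= 1L
    y[s$days[keep]] <- s$pct_change[keep]
    y
  }, numeric(max_day))
  if (is.null(dim(ymat))) ymat <- matrix(ymat, nrow = max_day)
  ylim <- range(c(ymat, tcl, -tcl), na.rm = TRUE)
  graphics::matplot(day_seq, ymat, type = "o", pch = 19, lty = 1,
                    col = seq_along(series), ylim = ylim,
                    xlab = "day", ylab = "Xt (%)",
                    main = sprintf("%s (%s)", series[[1L]]$analyte,
                                   series[[1L]]$material))
  graphics::abline(h = c(-tcl, tcl), lty = 2)
  graphics::legend("topleft",
                   legend = vapply(series, `[[`, "", "level"),
                   col = seq_along(series), lty = 1, pch = 19, bty = "n")
  invisible(path)
}
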