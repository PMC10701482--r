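#' Load the packaged reference stability study
#'
#' The package ships a hand-transcribed copy of a published 15/20-day
#' stability study of QC materials stored in a chemistry analyzer's
#' refrigerated storage module: 48 analyte/material combinations across
#' four control materials (MQ, serum multiqual, 26 analytes; UC, urine
#' chemistry, 13; LI, immunology, 6; LL, lipids, 3), each at two levels.
#' Because the publication prints only the derived daily percent changes
#' (not the raw triplicates), the fixtures carry `Xt%` series plus the
#' per-analyte printed TCL, the variation registry behind the TCLs, and
#' the reported verdicts.
#'
#' Three cells of the source table are internally inconsistent: their
#' printed magnitude exceeds the printed TCL although the table does not
#' mark them as exceedances, while *smaller* magnitudes in the same rows
#' are marked (no single threshold can explain the row). They are listed in
#' the `errata` element and, with `errata = "mask"` (default), removed from
#' the series as unreliable misprints; `errata = "printed"` keeps them at
#' face value.
#'
#' @param errata `"mask"` (default) or `"printed"`; see Details.
#' @return list of class `reference_study`:
#' \describe{
#'   \item{series}{list of `qc_series`, one per analyte/material/level
#'     (levels with no data, e.g. the unused high lipid level for APO A1,
#'     are kept as empty series).}
#'   \item{tcls}{data.frame `material, analyte, tcl` of printed TCLs.}
#'   \item{long}{long data.frame `material, analyte, level, day,
#'     pct_change, flagged` (`flagged` = marked as exceedance in print).}
#'   \item{registry}{`qc_registry` of CVa/CVb per analyte and matrix.}
#'   \item{reported_verdicts}{data.frame of the published per-analyte
#'     verdicts (`stable`, `onset_day`).}
#'   \item{errata}{data.frame describing the inconsistent cells.}
#'   \item{study_ends}{named vector: MQ 15, UC 15, LI 20, LL 20.}
#' }
#' @export
load_reference_study <- function(errata = c("mask", "printed")) {
  errata <- match.arg(errata)
  ext <- function(f) system.file("extdata", f, package = "qcstability",
                                 mustWork = TRUE)
  tabs <- rbind(
    read_pct_table(ext("reference_pct_change_mq_uc.csv"), 15L),
    read_pct_table(ext("reference_pct_change_ll_li.csv"), 20L)
  )
  err <- read.csv(ext("reference_errata.csv"), stringsAsFactors = FALSE)
  if (errata == "mask") {
    for (i in seq_len(nrow(err))) {
      hit <- tabs$material == err$material[i] & tabs$analyte == err$analyte[i] &
        tabs$level == err$level[i] & tabs$day == err$day[i]
      tabs$pct_change[hit] <- NA_real_
    }
  }
  tcls <- unique(tabs[, c("material", "analyte", "tcl")])
  rownames(tcls) <- NULL

  keys <- unique(tabs[, c("material", "analyte", "level")])
  series <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- tabs[tabs$material == keys$material[i] &
                 tabs$analyte == keys$analyte[i] &
                 tabs$level == keys$level[i], ]
    ok <- !is.na(rows$pct_change)
    qc_series(keys$analyte[i], keys$material[i], keys$level[i],
              days = rows$day[ok], pct_change = rows$pct_change[ok])
  })
  names(series) <- paste(keys$analyte, keys$material, keys$level, sep = "/")

  verd <- read.csv(ext("reference_verdicts.csv"), stringsAsFactors = FALSE)
  verd$stable <- as.logical(verd$stable)
  verd$onset_day <- as.integer(verd$onset_day)

  long <- tabs[, c("material", "analyte", "level", "day", "pct_change",
                   "flagged")]
  structure(
    list(series = series, tcls = tcls, long = long,
         registry = read_variation_registry(ext("variation_registry.csv")),
         reported_verdicts = verd, errata = err, errata_mode = errata,
         study_ends = c(MQ = 15L, UC = 15L, LI = 20L, LL = 20L)),
    class = "reference_study"
  )
}

# parse one wide fixture table: cells are printed values, "" for a result
# lost to an analyzer error, a trailing "*" marking cells the source table
# flags as exceedances
read_pct_table <- function(path, n_days) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  day_cols <- paste0("d", seq_len(n_days))
  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    cells <- trimws(unlist(raw[i, day_cols], use.names = FALSE))
    flagged <- grepl("\\*$", cells)
    num <- suppressWarnings(as.numeric(sub("\\*$", "", cells)))
    out[[i]] <- data.frame(
      material = raw$material[i], analyte = raw$analyte[i],
      level = raw$level[i], day = seq_len(n_days),
      pct_change = num, flagged = flagged & !is.na(num),
      tcl = as.numeric(raw$tcl[i]), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Re-run the reference study's stability assessment
#'
#' Applies [assess_panel()] with the given decision rule to the packaged
#' percent-change series and printed TCLs, reproducing the study's verdict
#' table offline.
#'
#' @inheritParams load_reference_study
#' @param rule a [decision_rule()].
#' @return A `qc_verdicts` data.frame (see [assess_panel()]); the loaded
#'   study is attached as `attr(, "study")`.
#' @export
#' @examples
#' v <- reproduce_study()
#' summarize_verdicts(v)$overall # 40 of 48 stable
reproduce_study <- function(rule = decision_rule(),
                            errata = c("mask", "printed")) {
  study <- load_reference_study(errata)
  out <- assess_panel(study$series, study$tcls, rule = rule,
                      study_ends = study$study_ends)
  attr(out, "study") <- study
  out
}
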