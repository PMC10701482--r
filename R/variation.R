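#' Read a registry of analytical and biological variation coefficients
#'
#' The registry holds one row per analyte and matrix with the analytical
#' coefficient of variation `cva` (%, from historical internal QC), the
#' within-subject biological variation `cvb` (%, from a curated database;
#' may be empty when no database lists the analyte in that matrix), and
#' `cvb_source` (`EFLM`, `Ricos`, or `none`).
#'
#' @param path CSV with columns `analyte, matrix, cva, cvb, cvb_source`.
#' @inheritParams read_measurements
#' @return A data.frame classed `qc_registry`, keyed by `(analyte, matrix)`;
#'   absent `cvb` is `NA`.
#' @export
read_variation_registry <- function(path, dialect = c("standard", "european")) {
  if (!file.exists(path))
    qc_abort(paste0("file not found: ", path), "qc_parse_error")
  dia <- csv_dialect(dialect)
  x <- read.csv(path, sep = dia$sep, dec = dia$dec, check.names = FALSE,
                fileEncoding = "UTF-8", strip.white = TRUE,
                stringsAsFactors = FALSE)
  need <- c("analyte", "matrix", "cva", "cvb", "cvb_source")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    qc_abort(paste0("registry lacks column(s): ", paste(miss, collapse = ", ")),
             "qc_parse_error")
  x$cva <- as.numeric(x$cva)
  x$cvb <- as.numeric(x$cvb)
  if (anyNA(x$cva) || any(x$cva < 0))
    qc_abort("cva must be a non-negative number for every registry row",
             "qc_validation_error")
  if (any(!is.na(x$cvb) & x$cvb < 0))
    qc_abort("cvb must be non-negative when present", "qc_validation_error")
  key <- paste(x$analyte, x$matrix, sep = "\r")
  if (anyDuplicated(key))
    qc_abort(paste0("duplicate registry entry for (",
                    sub("\r", ", ", key[duplicated(key)][1L]), ")"),
             "qc_uniqueness_error")
  class(x) <- c("qc_registry", "data.frame")
  x
}

#' Coefficient of variation of repeated QC results
#'
#' The lab-QC convention: 100 times the sample standard deviation
#' (`n - 1` denominator) over the mean.
#'
#' @param values numeric vector of positive results; `NA`s are dropped.
#' @return CV in percent.
#' @export
#' @examples
#' compute_cv(c(90, 100, 110)) # 10
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    qc_abort("need at least 2 non-missing values to estimate a CV",
             "qc_insufficient_data")
  m <- mean(values)
  if (m <= 0)
    qc_abort("mean of values must be positive", "qc_domain_error")
  100 * stats::sd(values) / m
}

#' Total Change Limit from analytical and biological variation
#'
#' The symmetric stability threshold applied to `|Xt%|`:
#' \deqn{TCL = \sqrt{(1.65\,CVa)^2 + (0.5\,CVb)^2}}
#' When no biological-variation estimate exists the CVa-only variant
#' \eqn{TCL = 1.65\,CVa} is used. The multipliers are exposed because other
#' stability studies use variant factors; the formula structure is fixed.
#'
#' @param cva analytical CV in percent (>= 0).
#' @param cvb within-subject biological CV in percent, or `NULL`/`NA` when
#'   no database value exists.
#' @param analyte,matrix optional labels carried on the result.
#' @param multipliers named numeric, multipliers for the two components.
#' @return A `tcl_spec` object with elements `tcl` (full precision),
#'   `variant` (`"full"` or `"cva_only"`), `cva`, `cvb`, `analyte`,
#'   `matrix`.
#' @export
#' @examples
#' compute_tcl(1.7, 13.9)$tcl # 7.4947...
#' compute_tcl(1.4)$variant   # "cva_only"
compute_tcl <- function(cva, cvb = NULL, analyte = NA_character_,
                        matrix = NA_character_,
                        multipliers = c(cva = 1.65, cvb = 0.5)) {
  if (length(cvb) == 0L || is.na(cvb)) cvb <- NULL
  if (is.na(cva) || cva < 0)
    qc_abort("cva must be a non-negative number", "qc_domain_error")
  if (!is.null(cvb) && cvb < 0)
    qc_abort("cvb must be non-negative when present", "qc_domain_error")
  if (is.null(cvb)) {
    tcl <- multipliers[["cva"]] * cva
    variant <- "cva_only"
  } else {
    tcl <- sqrt((multipliers[["cva"]] * cva)^2 + (multipliers[["cvb"]] * cvb)^2)
    variant <- "full"
  }
  structure(
    list(analyte = analyte, matrix = matrix, tcl = tcl, variant = variant,
         cva = cva, cvb = if (is.null(cvb)) NA_real_ else cvb,
         multipliers = multipliers),
    class = "tcl_spec"
  )
}

#' Wrap an externally supplied threshold as a TCL specification
#'
#' Used when the threshold is taken as given (e.g. a published table value)
#' rather than derived from CVa/CVb; `variant` is `"fixed"`.
#'
#' @param tcl threshold in percent (>= 0).
#' @inheritParams compute_tcl
#' @return A `tcl_spec` object.
#' @export
fixed_tcl <- function(tcl, analyte = NA_character_, matrix = NA_character_) {
  if (is.na(tcl) || tcl < 0)
    qc_abort("tcl must be a non-negative number", "qc_domain_error")
  structure(
    list(analyte = analyte, matrix = matrix, tcl = tcl, variant = "fixed",
         cva = NA_real_, cvb = NA_real_, multipliers = NULL),
    class = "tcl_spec"
  )
}

#' @export
print.tcl_spec <- function(x, ...) {
  cat(sprintf("TCL %.2f%% (%s)%s\n", x$tcl, x$variant,
              if (!is.na(x$analyte)) paste0(" for ", x$analyte) else ""))
  if (x$variant != "fixed")
    cat(sprintf("  cva = %s%%, cvb = %s%%\n", format(x$cva),
                if (is.na(x$cvb)) "-" else format(x$cvb)))
  invisible(x)
}

#' Compute TCLs for every registry entry
#'
#' @param registry a `qc_registry` (see [read_variation_registry()]).
#' @inheritParams compute_tcl
#' @return The registry with added columns `variant` and `tcl`.
#' @export
registry_tcls <- function(registry, multipliers = c(cva = 1.65, cvb = 0.5)) {
  specs <- lapply(seq_len(nrow(registry)), function(i)
    compute_tcl(registry$cva[i], registry$cvb[i],
                analyte = registry$analyte[i], matrix = registry$matrix[i],
                multipliers = multipliers))
  registry$variant <- vapply(specs, `[[`, "", "variant")
  registry$tcl <- vapply(specs, `[[`, 0, "tcl")
  registry
}

#' Classify analytical imprecision against biological-variation tiers
#'
#' The Fraser performance hierarchy grades imprecision by the ratio
#' `cva / cvb`: `optimal` when the ratio is at most 0.25, `desirable` up to
#' 0.50, `minimum` up to 0.75, and `fail` beyond. Boundary values belong to
#' the better tier. Analytes without a biological-variation estimate are
#' `not_classifiable` (distinct from `fail`).
#'
#' @inheritParams compute_tcl
#' @param fractions tier upper bounds as fractions of `cvb`.
#' @return data.frame with columns `cva`, `cvb`, `ratio`, `tier` (one row
#'   per input element; `cva` and `cvb` are recycled to a common length).
#' @export
#' @examples
#' classify_spec_tier(2.3, 5.3)$tier  # "desirable"
#' classify_spec_tier(2.3, 2.1)$tier  # "fail"
classify_spec_tier <- function(cva, cvb,
                               fractions = c(optimal = 0.25,
                                             desirable = 0.50,
                                             minimum = 0.75)) {
  n <- max(length(cva), length(cvb))
  cva <- rep_len(as.numeric(cva), n)
  cvb <- rep_len(as.numeric(cvb), n)
  if (any(!is.na(cva) & cva < 0))
    qc_abort("cva must be non-negative", "qc_domain_error")
  ratio <- ifelse(is.na(cvb) | cvb <= 0, NA_real_, cva / cvb)
  tier <- ifelse(is.na(ratio), "not_classifiable",
          ifelse(ratio <= fractions[["optimal"]], "optimal",
          ifelse(ratio <= fractions[["desirable"]], "desirable",
          ifelse(ratio <= fractions[["minimum"]], "minimum", "fail"))))
  data.frame(cva = cva, cvb = cvb, ratio = ratio, tier = tier,
             stringsAsFactors = FALSE)
}

#' Pre-run comparability check against historical QC limits
#'
#' Before each stability run the QC result(s) are checked against the
#' laboratory's historical mean +/- 2 SD; analytes outside the band are
#' recalibrated before the run counts.
#'
#' @param values current result(s) (a triplicate or a single value).
#' @param historical_mean,historical_sd historical QC mean and SD.
#' @return `TRUE` (pass) if every value lies within
#'   `historical_mean +/- 2 * historical_sd`, else `FALSE`.
#' @export
comparability_check <- function(values, historical_mean, historical_sd) {
  if (is.na(historical_sd) || historical_sd < 0)
    qc_abort("historical_sd must be non-negative", "qc_domain_error")
  lo <- historical_mean - 2 * historical_sd
  hi <- historical_mean + 2 * historical_sd
  all(values >= lo & values <= hi)
}
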