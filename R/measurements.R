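#' Coerce and validate a table of raw QC measurements
#'
#' A measurement table is long-format with one row per replicate result:
#' columns `analyte`, `material`, `level`, `day` (integer, 0 = baseline),
#' `replicate` (integer >= 1), `value` (result in the analyte's native
#' units), and optionally `missing` (logical; `TRUE` for analyzer-error gaps
#' where no result exists).
#'
#' @param x data.frame with at least the six columns above (`missing` is
#'   derived from `NA` values when absent).
#' @return The validated table, classed `qc_measurements`.
#' @details Validation enforces `day >= 0`, `replicate >= 1`, `value > 0`
#'   for non-missing rows, and uniqueness of
#'   `(analyte, material, level, day, replicate)`.
#' @export
#' @examples
#' qc_measurements(data.frame(
#'   analyte = "AST", material = "MQ", level = "low",
#'   day = 0, replicate = 1:3, value = c(100, 101, 102)
#' ))
qc_measurements <- function(x) {
  need <- c("analyte", "material", "level", "day", "replicate", "value")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    qc_abort(paste0("measurement table lacks column(s): ",
                    paste(miss, collapse = ", ")), "qc_parse_error")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$analyte  <- as.character(x$analyte)
  x$material <- as.character(x$material)
  x$level    <- as.character(x$level)
  x$day      <- as.integer(x$day)
  x$replicate <- as.integer(x$replicate)
  x$value    <- as.numeric(x$value)
  if (is.null(x$missing)) x$missing <- is.na(x$value)
  x$missing <- as.logical(x$missing)
  x$value[x$missing] <- NA_real_

  if (anyNA(x$day) || any(x$day < 0L))
    qc_abort("day must be a non-negative integer (0 = baseline)",
             "qc_validation_error")
  if (anyNA(x$replicate) || any(x$replicate < 1L))
    qc_abort("replicate must be an integer >= 1", "qc_validation_error")
  bad <- !x$missing & (is.na(x$value) | x$value <= 0)
  if (any(bad))
    qc_abort(paste0("non-missing values must be > 0 (rows ",
                    paste(utils::head(which(bad), 5L), collapse = ", "), ")"),
             "qc_validation_error")
  key <- paste(x$analyte, x$material, x$level, x$day, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    qc_abort(sprintf(
      "duplicate measurement key: analyte=%s material=%s level=%s day=%d replicate=%d",
      x$analyte[d], x$material[d], x$level[d], x$day[d], x$replicate[d]),
      "qc_uniqueness_error")
  }
  class(x) <- c("qc_measurements", "data.frame")
  x
}

csv_dialect <- function(dialect = c("standard", "european")) {
  dialect <- match.arg(dialect)
  if (dialect == "european") list(sep = ";", dec = ",")
  else list(sep = ",", dec = ".")
}

#' Read raw QC measurements from CSV
#'
#' Parses a long-format measurement CSV (see [qc_measurements()] for the
#' column contract). Value cells equal to one of the `sentinels` become
#' missing records (`missing = TRUE`), matching the convention of printing
#' an en dash for results lost to analyzer errors.
#'
#' @param path CSV file path.
#' @param dialect `"standard"` (comma separator, `.` decimal) or
#'   `"european"` (semicolon separator, `,` decimal).
#' @param sentinels character values of the `value` column interpreted as a
#'   missing result.
#' @return A `qc_measurements` data.frame.
#' @export
read_measurements <- function(path, dialect = c("standard", "european"),
                              sentinels = c("", "NA", "na", "–", "-")) {
  if (!file.exists(path))
    qc_abort(paste0("file not found: ", path), "qc_parse_error")
  dia <- csv_dialect(dialect)
  raw <- read.csv(path, sep = dia$sep, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8",
                  strip.white = TRUE)
  need <- c("analyte", "material", "level", "day", "replicate", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    qc_abort(paste0("header lacks column(s): ", paste(miss, collapse = ", ")),
             "qc_parse_error")
  val_chr <- trimws(raw$value)
  val_chr[is.na(val_chr)] <- "" # read.csv already folded literal "NA"
  missing <- val_chr %in% sentinels
  if (dia$dec != ".") val_chr <- gsub(dia$dec, ".", val_chr, fixed = TRUE)
  value <- suppressWarnings(as.numeric(val_chr))
  bad <- !missing & is.na(value)
  if (any(bad))
    qc_abort(paste0("malformed numeric value in row(s) ",
                    paste(utils::head(which(bad), 5L), collapse = ", "),
                    " of ", path), "qc_parse_error")
  for (col in c("day", "replicate")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v))
      qc_abort(paste0("malformed numeric in column '", col, "' of ", path),
               "qc_parse_error")
    raw[[col]] <- v
  }
  qc_measurements(data.frame(
    analyte = raw$analyte, material = raw$material, level = raw$level,
    day = raw$day, replicate = raw$replicate,
    value = value, missing = missing, stringsAsFactors = FALSE
  ))
}

#' Write QC measurements to CSV
#'
#' Values are serialised with 17 significant digits so that
#' `read_measurements(write_measurements(x))` round-trips doubles
#' bit-exactly. Missing results are written as empty cells.
#'
#' @param x `qc_measurements` table.
#' @param path output CSV path.
#' @inheritParams read_measurements
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path, dialect = c("standard", "european")) {
  x <- qc_measurements(x)
  dia <- csv_dialect(dialect)
  val <- ifelse(x$missing, "", sprintf("%.17g", x$value))
  if (dia$dec != ".") val <- gsub(".", dia$dec, val, fixed = TRUE)
  out <- data.frame(
    analyte = x$analyte, material = x$material, level = x$level,
    day = x$day, replicate = x$replicate, value = val,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = dia$sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
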