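#' Analysis configuration
#'
#' Collects the tunable constants of the pipeline in one list: the TCL
#' multipliers, the Fraser tier fractions, the decision rule, per-material
#' study windows, the material-to-matrix translation, display rounding and
#' the CSV dialect. `stability_config()` returns the defaults, optionally
#' overridden; `read_config()` loads a YAML file with the same structure
#' (see `inst/extdata/default_config.yaml`) and fills unset entries with
#' the defaults.
#'
#' @param ... named overrides of the default entries (partial lists are
#'   merged recursively).
#' @return A named list classed `qc_config`.
#' @export
stability_config <- function(...) {
  cfg <- list(
    tcl = list(cva_multiplier = 1.65, cvb_multiplier = 0.5),
    tier_fractions = c(optimal = 0.25, desirable = 0.50, minimum = 0.75),
    rule = list(min_days = 2L, consecutive = FALSE),
    study_ends = c(MQ = 15L, UC = 15L, LI = 20L, LL = 20L),
    matrix_map = c(MQ = "serum", LI = "serum", LL = "serum", UC = "urine"),
    rounding_digits = 2L,
    csv_dialect = "standard"
  )
  dots <- list(...)
  if (length(dots) > 0L) cfg <- modifyList(cfg, dots)
  structure(cfg, class = "qc_config")
}

#' @rdname stability_config
#' @param path YAML configuration file.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    qc_abort(paste0("config file not found: ", path), "qc_config_error")
  y <- yaml::read_yaml(path)
  defaults <- stability_config()
  cfg <- modifyList(defaults, y)
  # yaml returns lists where the defaults are named vectors
  for (f in c("tier_fractions", "study_ends", "matrix_map"))
    if (is.list(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  cfg$rule$min_days <- as.integer(cfg$rule$min_days)
  structure(cfg, class = "qc_config")
}

# helpers lifting config pieces into the module objects
config_rule <- function(cfg) decision_rule(cfg$rule$min_days,
                                           cfg$rule$consecutive)
config_multipliers <- function(cfg) c(cva = cfg$tcl$cva_multiplier,
                                      cvb = cfg$tcl$cvb_multiplier)
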