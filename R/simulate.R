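#' Phenomenological degradation model for synthetic QC series
#'
#' Describes the systematic percent deviation `D(t)` of a degrading
#' analyte at study day `t` (the baseline day 0 always has `D(0) = 0`):
#' \describe{
#'   \item{none}{`D(t) = 0`.}
#'   \item{linear}{`D(t) = sign * rate * t`.}
#'   \item{delayed_linear}{`D(t) = sign * rate * max(0, t - onset + 1)` -
#'     degradation starts at day `onset`.}
#'   \item{step}{`D(t) = sign * shift` for `t >= onset`, else 0.}
#' }
#'
#' @param kind drift type.
#' @param rate drift in percent per day (>= 0), for the linear kinds.
#' @param onset first degraded day (>= 1), for `delayed_linear` and `step`.
#' @param shift instantaneous percent change of the `step` kind.
#' @param sign `+1` (concentration rises) or `-1` (falls).
#' @return A `drift_model` object.
#' @export
drift_model <- function(kind = c("none", "linear", "delayed_linear", "step"),
                        rate = 0, onset = 1L, shift = 0, sign = 1) {
  kind <- match.arg(kind)
  if (rate < 0) qc_abort("rate must be >= 0", "qc_domain_error")
  if (onset < 1) qc_abort("onset must be >= 1", "qc_domain_error")
  if (!sign %in% c(-1, 1)) qc_abort("sign must be +1 or -1", "qc_domain_error")
  structure(list(kind = kind, rate = rate, onset = as.integer(onset),
                 shift = shift, sign = sign),
            class = "drift_model")
}

#' Systematic deviation of a drift model at given days
#'
#' @param drift a [drift_model()].
#' @param day integer day(s), 0 = baseline.
#' @return Percent deviations `D(day)`; `D(0)` is always 0.
#' @export
drift_pct <- function(drift, day) {
  stopifnot(inherits(drift, "drift_model"))
  d <- switch(drift$kind,
    none = rep(0, length(day)),
    linear = drift$sign * drift$rate * day,
    delayed_linear = drift$sign * drift$rate * pmax(0, day - drift$onset + 1),
    step = drift$sign * drift$shift * as.numeric(day >= drift$onset)
  )
  d[day == 0] <- 0
  d
}

#' Design of a synthetic QC stability experiment
#'
#' @param analytes data.frame with one row per analyte/level: columns
#'   `analyte`, `level`, `mean` (true concentration, > 0) and `cva` (true
#'   analytical CV in percent, >= 0).
#' @param days number of study days after the baseline.
#' @param replicates replicates per day (>= 1; QC practice is triplicate).
#' @param material material code stamped on the simulated records.
#' @param seed integer seed; identical seed and design give an identical
#'   dataset.
#' @return A `simulation_design` object.
#' @export
simulation_design <- function(analytes, days = 15L, replicates = 3L,
                              material = "SIM", seed = NULL) {
  need <- c("analyte", "level", "mean", "cva")
  if (!is.data.frame(analytes) || !all(need %in% names(analytes)))
    qc_abort("analytes must be a data.frame with columns analyte, level, mean, cva",
             "qc_validation_error")
  if (any(analytes$mean <= 0))
    qc_abort("true means must be positive", "qc_domain_error")
  if (any(analytes$cva < 0))
    qc_abort("true cva must be >= 0", "qc_domain_error")
  if (replicates < 1L) qc_abort("replicates must be >= 1", "qc_domain_error")
  if (days < 1L) qc_abort("days must be >= 1", "qc_domain_error")
  structure(list(analytes = as.data.frame(analytes), days = as.integer(days),
                 replicates = as.integer(replicates),
                 material = as.character(material),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_design")
}

# drift spec for one analyte/level: `drift` may be a single drift_model for
# the whole panel, or a named list keyed "analyte:level" or "analyte"
resolve_drift <- function(drift, analyte, level) {
  if (is.null(drift)) return(drift_model("none"))
  if (inherits(drift, "drift_model")) return(drift)
  if (is.list(drift)) {
    hit <- drift[[paste(analyte, level, sep = ":")]] %||% drift[[analyte]]
    if (is.null(hit)) return(drift_model("none"))
    stopifnot(inherits(hit, "drift_model"))
    return(hit)
  }
  qc_abort("drift must be a drift_model or a named list of them",
           "qc_validation_error")
}

#' Simulate raw QC measurements with known noise and degradation
#'
#' Each replicate is drawn as
#' `value = mean * (1 + D(t)/100) * (1 + eps)`, with `eps` independent
#' zero-mean Gaussian noise of standard deviation `cva/100` (multiplicative
#' noise, i.e. constant CV, truncated at -99% as a positivity guard) and
#' `D(t)` the analyte's [drift_model()]. The baseline day 0 carries the
#' same noise as study days and never drifts.
#'
#' @param design a [simulation_design()].
#' @param drift a [drift_model()] for the whole panel, or a named list
#'   keyed by `"analyte"` or `"analyte:level"` (unmatched entries get no
#'   drift).
#' @return A `qc_measurements` table covering days `0..days`.
#' @export
#' @examples
#' d <- simulation_design(
#'   data.frame(analyte = "A", level = "low", mean = 100, cva = 0),
#'   days = 5, seed = 1
#' )
#' m <- simulate_measurements(d, drift_model("linear", rate = 1))
#' m$value[m$day == 5] # exactly 105
simulate_measurements <- function(design, drift = drift_model("none")) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  an <- design$analytes
  days <- 0:design$days
  reps <- seq_len(design$replicates)
  out <- vector("list", nrow(an))
  for (i in seq_len(nrow(an))) {
    dm <- resolve_drift(drift, an$analyte[i], an$level[i])
    grid <- expand.grid(replicate = reps, day = days)
    dpct <- drift_pct(dm, grid$day)
    eps <- pmax(rnorm(nrow(grid), 0, an$cva[i] / 100), -0.99)
    out[[i]] <- data.frame(
      analyte = an$analyte[i], material = design$material,
      level = an$level[i], day = grid$day, replicate = grid$replicate,
      value = an$mean[i] * (1 + dpct / 100) * (1 + eps),
      missing = FALSE, stringsAsFactors = FALSE
    )
  }
  qc_measurements(do.call(rbind, out))
}

#' Simulate historical QC results for CVa estimation
#'
#' Emulates months of routine internal QC: i.i.d. multiplicative-noise
#' draws around a stable mean, from which [compute_cv()] recovers the true
#' CV as `n` grows.
#'
#' @param n_days number of results (>= 2).
#' @param mean true concentration (> 0).
#' @param cva_true true analytical CV in percent.
#' @param seed optional integer seed.
#' @return Numeric vector of simulated results.
#' @export
simulate_historical_qc <- function(n_days, mean, cva_true, seed = NULL) {
  if (n_days < 2L) qc_abort("n_days must be >= 2", "qc_domain_error")
  if (mean <= 0) qc_abort("mean must be positive", "qc_domain_error")
  if (cva_true < 0) qc_abort("cva_true must be >= 0", "qc_domain_error")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mean * (1 + pmax(rnorm(n_days, 0, cva_true / 100), -0.99))
}

# noiseless loss-of-stability day for a drift model under a rule, or NA:
# the verdict obtained when cva = 0 (the deterministic limit)
noiseless_onset <- function(drift, tcl, rule, study_end) {
  days <- seq_len(study_end)
  exc <- days[abs(drift_pct(drift, days)) > tcl]
  level_onset(exc, rule)
}

#' Operating characteristics of the TCL decision rule
#'
#' Monte-Carlo study of the rule on synthetic panels: for each drift rate
#' in `rates`, simulates `n_reps` independent analytes (each with `levels`
#' control levels measured in `replicates` per day over `days` study days),
#' assesses every replicate with [assess_stability()], and tabulates the
#' probability of an unstable verdict and the mean detection delay against
#' the noiseless onset. A rate of 0 gives the false-alarm probability.
#'
#' @param rates drift rates in percent per day (a grid; 0 allowed).
#' @param tcl threshold in percent.
#' @param cva true analytical CV in percent.
#' @param rule a [decision_rule()].
#' @param days,replicates,levels panel geometry.
#' @param kind,onset,sign drift shape passed to [drift_model()] (rate comes
#'   from `rates`).
#' @param n_reps Monte-Carlo replicates per grid point.
#' @param seed integer seed for reproducibility.
#' @return data.frame with one row per rate: `rate`, `noiseless_onset`
#'   (`NA` when the drift never crosses the TCL), `p_unstable`,
#'   `mean_delay` (mean of detected onset minus noiseless onset, among
#'   detections; `NA` when undefined), `n_reps`.
#' @export
operating_characteristics <- function(rates, tcl, cva,
                                      rule = decision_rule(),
                                      days = 15L, replicates = 3L,
                                      levels = 2L,
                                      kind = "linear", onset = 1L, sign = 1,
                                      n_reps = 100L, seed = NULL) {
  if (n_reps < 1L) qc_abort("n_reps must be >= 1", "qc_domain_error")
  if (!is.null(seed)) set.seed(as.integer(seed))
  day_seq <- seq_len(days)
  out <- vector("list", length(rates))
  for (r in seq_along(rates)) {
    dm <- drift_model(kind, rate = rates[r], onset = onset, sign = sign)
    target <- noiseless_onset(dm, tcl, rule, days)
    dpct <- drift_pct(dm, day_seq)
    detected <- logical(n_reps)
    onsets <- rep(NA_integer_, n_reps)
    for (rep_i in seq_len(n_reps)) {
      level_onsets <- rep(NA_integer_, levels)
      for (lv in seq_len(levels)) {
        # day means of `replicates` multiplicative-noise replicates
        noise <- pmax(matrix(rnorm((days + 1L) * replicates, 0, cva / 100),
                             nrow = days + 1L), -0.99)
        mu <- c(1, 1 + dpct / 100) # relative true level, day 0 first
        mean_by_day <- rowMeans(1 + noise) * mu
        xo <- mean_by_day[1L]
        pct <- 100 * (mean_by_day[-1L] - xo) / xo
        level_onsets[lv] <- level_onset(day_seq[abs(pct) > tcl], rule)
      }
      if (any(!is.na(level_onsets))) {
        detected[rep_i] <- TRUE
        onsets[rep_i] <- min(level_onsets, na.rm = TRUE)
      }
    }
    out[[r]] <- data.frame(
      rate = rates[r], noiseless_onset = target,
      p_unstable = mean(detected),
      mean_delay = if (any(detected) && !is.na(target))
        mean(onsets[detected] - target) else NA_real_,
      n_reps = n_reps
    )
  }
  do.call(rbind, out)
}
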