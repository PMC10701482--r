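# Independent brute-force evaluator of the loss-of-stability rule.
# Enumerates every subset of min_days exceedance days per level (combn),
# keeps those satisfying the rule, and takes the earliest first day --
# a different path from the package's run/count logic.
oracle_assess <- function(series_list, tcl, min_days, consecutive,
                          study_end) {
  onsets <- integer(0)
  for (s in series_list) {
    keep <- s$days >= 1 & abs(s$pct_change) > tcl
    exc <- s$days[keep]
    if (length(exc) < min_days) next
    # index-based combn: a length-one `exc` must not be read as seq_len(n)
    subs <- matrix(exc[utils::combn(seq_along(exc), min_days)],
                   nrow = min_days)
    ok <- if (consecutive && min_days > 1) {
      apply(subs, 2, function(x) all(diff(sort(x)) == 1))
    } else rep(TRUE, ncol(subs))
    if (any(ok)) onsets <- c(onsets, min(subs[1, ok]))
  }
  if (length(onsets) == 0) {
    list(stable = TRUE, onset = NA_integer_, max_storage = study_end)
  } else {
    list(stable = FALSE, onset = min(onsets), max_storage = min(onsets) - 1L)
  }
}

# random multi-level percent-change series for rule fuzzing
random_series_set <- function(n_levels, n_days, sd = 3) {
  lapply(seq_len(n_levels), function(lv) {
    days <- sort(sample(seq_len(n_days), max(1, rbinom(1, n_days, 0.8))))
    qc_series("X", "SIM", paste0("L", lv), days = days,
              pct_change = rnorm(length(days), 0, sd))
  })
}

# small measurement table builder
make_measurements <- function(analyte = "A", material = "MQ", level = "low",
                              day_values) {
  rows <- do.call(rbind, lapply(seq_along(day_values), function(i) {
    v <- day_values[[i]]
    data.frame(analyte = analyte, material = material, level = level,
               day = as.integer(names(day_values)[i]),
               replicate = seq_along(v), value = v,
               stringsAsFactors = FALSE)
  }))
  qc_measurements(rows)
}
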