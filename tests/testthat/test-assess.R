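ref <- load_reference_study()

test_that("exceedance comparison is strict on the absolute value", {
  s <- qc_series("ALP", "MQ", "high", days = c(8, 14), pct_change = c(4.666, -4.48))
  expect_equal(exceedance_days(s, 4.66), 8L)   # 4.666 > 4.66 exceeds
  expect_equal(exceedance_days(s, 4.666), integer(0)) # equality does not
  s2 <- qc_series("LDH", "MQ", "low", days = 14, pct_change = -4.48)
  expect_length(exceedance_days(s2, 4.55), 0L) # |-4.48| < 4.55
  s3 <- qc_series("X", "SIM", "l", days = 1:3, pct_change = c(0, 0, 0))
  expect_length(exceedance_days(s3, 0.5), 0L)
})

test_that("a mismatched analyte between series and TCL spec is rejected", {
  s <- qc_series("ALT", "MQ", "low", days = 1, pct_change = 1)
  expect_error(exceedance_days(s, compute_tcl(2, 5, analyte = "AST")),
               class = "qc_validation_error")
})

test_that("two exceedance days at a level declare instability from the first; one never does", {
  two <- qc_series("X", "SIM", "low", days = 1:10,
                   pct_change = c(0, 0, 0, 6, 0, 0, 6, 0, 0, 0))
  one <- qc_series("X", "SIM", "high", days = 1:10,
                   pct_change = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 7))
  v <- assess_stability(list(two, one), 5, decision_rule(), study_end = 10)
  expect_false(v$stable)
  expect_equal(v$onset_day, 4L)
  expect_equal(v$max_storage_days, 3L)
  expect_equal(v$qualifying_levels, "low")

  v1 <- assess_stability(one, 5, decision_rule(), study_end = 10)
  expect_true(v1$stable)
  expect_equal(v1$max_storage_days, 10L)
})

test_that("levels with no data are skipped; an all-empty set errors", {
  empty <- qc_series("X", "SIM", "high", days = integer(0),
                     pct_change = numeric(0))
  ok <- qc_series("X", "SIM", "low", days = 1:3, pct_change = c(0, 0, 0))
  v <- assess_stability(list(ok, empty), 5, study_end = 3)
  expect_true(v$stable)
  expect_error(assess_stability(list(empty), 5, study_end = 3),
               class = "qc_no_data")
})

test_that("verdicts are invariant under sign flips of the whole series", {
  set.seed(31)
  for (i in 1:25) {
    ser <- random_series_set(n_levels = 2, n_days = 15, sd = 4)
    neg <- lapply(ser, function(s) {
      s$pct_change <- -s$pct_change
      s
    })
    tcl <- runif(1, 2, 6)
    v1 <- assess_stability(ser, tcl, study_end = 15)
    v2 <- assess_stability(neg, tcl, study_end = 15)
    expect_identical(v1$stable, v2$stable)
    expect_identical(v1$onset_day, v2$onset_day)
    expect_identical(v1$evidence, v2$evidence)
  }
})

test_that("raising the TCL never creates exceedances or destabilises a verdict", {
  set.seed(57)
  for (i in 1:25) {
    ser <- random_series_set(n_levels = 2, n_days = 15, sd = 4)
    tcl <- runif(1, 1, 6)
    up <- tcl + runif(1, 0.1, 4)
    for (s in ser)
      expect_true(all(exceedance_days(s, up) %in% exceedance_days(s, tcl)))
    v_lo <- assess_stability(ser, tcl, study_end = 15)
    v_hi <- assess_stability(ser, up, study_end = 15)
    if (v_lo$stable) expect_true(v_hi$stable)
  }
})

test_that("assess_stability agrees with a brute-force subset-enumeration oracle", {
  set.seed(99)
  for (i in 1:200) {
    n_days <- sample(5:20, 1)
    ser <- random_series_set(sample(1:3, 1), n_days, sd = 4)
    tcl <- runif(1, 1, 8)
    rule <- decision_rule(sample(1:3, 1), sample(c(TRUE, FALSE), 1))
    got <- assess_stability(ser, tcl, rule, study_end = n_days)
    want <- oracle_assess(ser, tcl, rule$min_days, rule$consecutive, n_days)
    expect_identical(got$stable, want$stable)
    expect_identical(got$onset_day, want$onset)
    expect_identical(got$max_storage_days, as.integer(want$max_storage))
  }
})

test_that("the verbatim three-consecutive-days rule shifts the reference verdicts as the data dictate", {
  verbatim <- decision_rule(min_days = 3, consecutive = TRUE)
  v <- reproduce_study(rule = verbatim)
  v_def <- reproduce_study()
  # LDH's evidence (days 13 and 15 only) no longer qualifies
  expect_true(v$stable[v$analyte == "LDH" & v$material == "MQ"])
  # ALP still fails, but only from its 3-day run at days 11-13
  expect_equal(v$onset_day[v$analyte == "ALP" & v$material == "MQ"], 11L)
  # CL (urine) moves from day 8 to its consecutive run at days 10-12
  expect_equal(v$onset_day[v$analyte == "CL" & v$material == "UC"], 10L)
  # trend-driven losses are unchanged
  for (a in c("AST", "Ca", "TBil")) {
    expect_equal(v$onset_day[v$analyte == a & v$material == "MQ"],
                 v_def$onset_day[v_def$analyte == a & v_def$material == "MQ"])
  }
  expect_equal(v$onset_day[v$analyte == "Glu" & v$material == "UC"], 8L)
  expect_equal(v$onset_day[v$analyte == "Trf" & v$material == "LI"], 18L)
})

test_that("assess_panel resolves TCLs, reports offenders, and handles empty panels", {
  ser <- list(qc_series("AST", "MQ", "low", 1:3, c(0, 0, 0)))
  tcls <- data.frame(analyte = "ALT", material = "MQ", tcl = 5)
  expect_error(assess_panel(ser, tcls, study_ends = c(MQ = 15)),
               "AST", class = "qc_config_error")
  expect_error(assess_panel(ser, data.frame(analyte = "AST", material = "MQ",
                                            tcl = 5),
                            study_ends = c(UC = 15)),
               class = "qc_config_error")
  v <- assess_panel(list(), tcls, study_ends = c(MQ = 15))
  expect_equal(nrow(v), 0L)
  expect_equal(summarize_verdicts(v)$overall, c(stable = 0L, total = 0L))
})

test_that("a matrix-keyed TCL table routes serum and urine materials correctly", {
  reg <- registry_tcls(ref$registry)
  ser <- list(
    qc_series("Glu", "MQ", "low", 1:3, c(0, 0, 0)),
    qc_series("Glu", "UC", "low", 1:3, c(2.8, 2.8, 2.8))
  )
  v <- assess_panel(ser, reg, study_ends = c(MQ = 15, UC = 15))
  # urine Glu TCL is CVa-only 1.65*1.6 = 2.64 < 2.8, serum is larger
  expect_true(v$stable[v$material == "MQ"])
  expect_false(v$stable[v$material == "UC"])
})
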