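design2 <- function(cva = 2, days = 15, seed = NULL, mean = 100)
  simulation_design(
    data.frame(analyte = "A", level = c("low", "high"),
               mean = mean, cva = cva),
    days = days, replicates = 3, seed = seed
  )

test_that("noiseless linear drift produces exact values and exact slopes", {
  d <- simulation_design(data.frame(analyte = "A", level = "low",
                                    mean = 100, cva = 0),
                         days = 10, seed = 1)
  m <- simulate_measurements(d, drift_model("linear", rate = 1))
  expect_equal(unique(m$value[m$day == 5]), 105)
  expect_equal(unique(m$value[m$day == 0]), 100)
  s <- build_series(m)
  study <- s$days >= 1
  fit <- lm(s$pct_change[study] ~ s$days[study])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-12)

  m_dn <- simulate_measurements(d, drift_model("delayed_linear", rate = 2,
                                               onset = 4, sign = -1))
  s_dn <- build_series(m_dn)
  expect_equal(s_dn$pct_change[s_dn$days == 3], 0)
  expect_equal(s_dn$pct_change[s_dn$days == 6], -6)
  m_st <- simulate_measurements(d, drift_model("step", shift = 5, onset = 7))
  s_st <- build_series(m_st)
  expect_equal(s_st$pct_change[s_st$days == 6], 0)
  expect_equal(s_st$pct_change[s_st$days == 10], 5)
})

test_that("identical seed and design give identical datasets and OC tables", {
  m1 <- simulate_measurements(design2(seed = 77))
  m2 <- simulate_measurements(design2(seed = 77))
  expect_identical(m1, m2)
  m3 <- simulate_measurements(design2(seed = 78))
  expect_false(identical(m1$value, m3$value))

  oc1 <- operating_characteristics(c(0, 1), tcl = 3.3, cva = 2,
                                   n_reps = 30, seed = 5)
  oc2 <- operating_characteristics(c(0, 1), tcl = 3.3, cva = 2,
                                   n_reps = 30, seed = 5)
  expect_identical(oc1, oc2)
})

test_that("simulated CSVs are byte-identical under a fixed seed", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(simulate_measurements(design2(seed = 123)), p1)
  write_measurements(simulate_measurements(design2(seed = 123)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("without drift the percent-change null is calibrated", {
  # Xt% ~ 100 * (Mt - Mo)/Mo with Mo, Mt each a mean of 3 draws of CV 2%:
  # mean 0, sd ~ cva * sqrt(2/3)
  set.seed(200)
  d10 <- replicate(200, {
    m <- simulate_measurements(design2(cva = 2, days = 10))
    s <- build_series(m[m$level == "low", ])
    s$pct_change[s$days == 10]
  })
  expect_equal(mean(d10), 0, tolerance = 0.2)
  expect_equal(sd(d10), 2 * sqrt(2 / 3), tolerance = 0.35)
})

test_that("historical QC simulation feeds CVa estimation", {
  x <- simulate_historical_qc(10000, 100, 2, seed = 3)
  cv <- compute_cv(x)
  expect_gte(cv, 1.9); expect_lte(cv, 2.1)
  y1 <- simulate_historical_qc(100, 100, 2, seed = 4)
  y2 <- simulate_historical_qc(100, 100, 2, seed = 5)
  expect_false(identical(y1, y2))
})

test_that("noiseless operating characteristics hit the closed-form onset", {
  oc <- operating_characteristics(rates = c(0.7, 1.3), tcl = 3.3, cva = 0,
                                  days = 15, n_reps = 3, seed = 9)
  expect_equal(oc$p_unstable, c(1, 1))
  expect_equal(oc$noiseless_onset, ceiling(3.3 / c(0.7, 1.3)))
  expect_equal(oc$mean_delay, c(0, 0))
})

test_that("a huge TCL yields no false alarms", {
  oc <- operating_characteristics(rates = 0, tcl = 50, cva = 1,
                                  days = 15, n_reps = 100, seed = 21)
  expect_equal(oc$p_unstable, 0)
})
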