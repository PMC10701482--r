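test_that("compute_cv matches the lab convention sd/mean*100", {
  expect_equal(compute_cv(c(5, 5, 5, 5)), 0)
  expect_equal(compute_cv(c(90, 100, 110)), 10)
  expect_error(compute_cv(c(3)), class = "qc_insufficient_data")
  expect_error(compute_cv(c(-2, 2)), class = "qc_domain_error")
})

test_that("compute_cv recovers the generator's set CV at large n", {
  x <- simulate_historical_qc(1000, mean = 80, cva_true = 2, seed = 11)
  expect_equal(compute_cv(x), 2, tolerance = 0.15 / 2)
  expect_equal(compute_cv(simulate_historical_qc(50, 80, 0, seed = 1)), 0)
})

test_that("compute_tcl implements the full and CVa-only variants", {
  expect_equal(round(compute_tcl(1.7, 13.9)$tcl, 2), 7.49)
  expect_equal(round(compute_tcl(1.0, 26.5)$tcl, 2), 13.35)
  expect_equal(compute_tcl(0, 0)$tcl, 0)
  spec <- compute_tcl(1.4)
  expect_equal(round(spec$tcl, 2), 2.31)
  expect_identical(spec$variant, "cva_only")
  expect_identical(compute_tcl(1.4, NA)$variant, "cva_only")
  expect_error(compute_tcl(-1, 5), class = "qc_domain_error")
})

test_that("TCL is monotone in both CVs, scales linearly, and cvb=0 equals absent", {
  grid <- expand.grid(cva = c(0, 0.5, 1.3, 2.2, 5), cvb = c(0, 2, 9.6, 30))
  tclv <- mapply(function(a, b) compute_tcl(a, b)$tcl, grid$cva, grid$cvb)
  for (i in seq_len(nrow(grid))) {
    expect_gte(compute_tcl(grid$cva[i] + 0.1, grid$cvb[i])$tcl, tclv[i])
    expect_gte(compute_tcl(grid$cva[i], grid$cvb[i] + 0.1)$tcl, tclv[i])
    for (k in c(0, 0.5, 2, 7))
      expect_equal(compute_tcl(k * grid$cva[i], k * grid$cvb[i])$tcl,
                   k * tclv[i])
  }
  expect_equal(compute_tcl(2.3, 0)$tcl, compute_tcl(2.3)$tcl)
  expect_gte(compute_tcl(2.3, 5)$tcl, 1.65 * 2.3)
})

test_that("tier classification applies the 0.25/0.50/0.75 fractions, boundaries inclusive", {
  expect_identical(classify_spec_tier(2.3, 5.3)$tier, "desirable")
  expect_identical(classify_spec_tier(1.9, 2.6)$tier, "minimum")
  expect_identical(classify_spec_tier(2.3, 2.1)$tier, "fail")
  expect_identical(classify_spec_tier(1.0, 26.5)$tier, "optimal")
  for (c0 in c(1, 5.3, 26.5)) {
    expect_identical(classify_spec_tier(0.25 * c0, c0)$tier, "optimal")
    expect_identical(classify_spec_tier(0.25 * c0 + 1e-9 * c0, c0)$tier,
                     "desirable")
    expect_identical(classify_spec_tier(0.75 * c0, c0)$tier, "minimum")
  }
  expect_identical(classify_spec_tier(2, NA)$tier, "not_classifiable")
})

test_that("comparability check passes iff every value is within mean +/- 2 SD", {
  expect_true(comparability_check(101, 100, 1))
  expect_false(comparability_check(103, 100, 1))
  expect_false(comparability_check(c(98, 100, 102.1), 100, 1))
  expect_true(comparability_check(c(98, 100, 102), 100, 1))
})

test_that("the variation registry reader validates and keys entries", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("analyte,matrix,cva,cvb,cvb_source",
               "CL,urine,1.4,,none",
               "UN,serum,1.7,13.9,EFLM"), path)
  reg <- read_variation_registry(path)
  expect_true(is.na(reg$cvb[reg$analyte == "CL"]))
  expect_equal(reg$cvb[reg$analyte == "UN"], 13.9)
  writeLines(c("analyte,matrix,cva,cvb,cvb_source",
               "X,serum,-1,5,EFLM"), path)
  expect_error(read_variation_registry(path), class = "qc_validation_error")
  writeLines(c("analyte,matrix,cva,cvb,cvb_source",
               "X,serum,1,5,EFLM",
               "X,serum,2,5,EFLM"), path)
  expect_error(read_variation_registry(path), class = "qc_uniqueness_error")
})
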