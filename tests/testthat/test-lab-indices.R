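test_that("FCPR flooring applies the detection limit with provenance", {
  expect_equal(floor_fcpr(NA, below_limit = TRUE),
               list(fcpr = 0.001, below_limit = TRUE))
  expect_equal(floor_fcpr(0.0005), list(fcpr = 0.001, below_limit = TRUE))
  expect_equal(floor_fcpr(0.47), list(fcpr = 0.47, below_limit = FALSE))
  expect_error(floor_fcpr(NA), "below-limit")
})

test_that("single-draw indices follow their printed formulas", {
  expect_equal(ga_a1c_ratio(25.9, 8.9), 25.9 / 8.9)   # ~2.910
  expect_equal(ga_a1c_ratio(8.9, 8.9), 1)
  expect_gt(ga_a1c_ratio(26, 8.9), ga_a1c_ratio(25, 8.9))
  expect_equal(fcpr_index(0.3, 10), 3)
  expect_equal(fcpr_index(0.001, 10), 0.01)
  expect_equal(fcpr_index(0.3, 20), fcpr_index(0.3, 10) / 2)
  expect_error(ga_a1c_ratio(-1, 8), "positive")
  expect_error(fcpr_index(0.3, 0), "positive")
})

test_that("HbA1c standard conversions match the harmonisation constants", {
  expect_equal(convert_hba1c(8.5, "jds_percent", "ngsp_percent"), 8.9)
  ifcc <- convert_hba1c(8.9, "ngsp_percent", "ifcc_mmol_mol")
  expect_equal(ifcc, 10.93 * 8.9 - 23.50)    # 73.777, prints as 73-74
  expect_equal(round(ifcc), 74)
  # round-trips across all three standards within 0.05 %-units
  for (a in c("jds_percent", "ngsp_percent", "ifcc_mmol_mol"))
    for (b in c("jds_percent", "ngsp_percent", "ifcc_mmol_mol")) {
      x <- if (a == "ifcc_mmol_mol") 73 else 8.5
      expect_lt(abs(convert_hba1c(convert_hba1c(x, a, b), b, a) - x), 0.05)
    }
  expect_error(convert_hba1c(55, "ngsp_percent", "ifcc_mmol_mol"), "plausible")
})

test_that("risk classification partitions the plane into three regions", {
  expect_equal(classify_risk(3.2, 0.4)$group, "high_variability")
  expect_equal(classify_risk(2.7, 5.6)$group, "low_variability")
  expect_equal(classify_risk(3.0, 5.0)$group, "indeterminate")
  expect_equal(classify_risk(2.5, 1.0)$group, "indeterminate")
  # printed boundary conventions: ratio >= 2.8 high-side, index < 3.0
  expect_equal(classify_risk(2.8, 2.9)$group, "high_variability")
  expect_equal(classify_risk(2.79, 3.0)$group, "low_variability")
  expect_equal(classify_risk(2.8, 3.0)$group, "indeterminate")
  # every point gets exactly one group
  set.seed(5)
  g <- classify_risk(runif(500, 1, 5), runif(500, 0, 10))$group
  expect_true(all(g %in% c("high_variability", "low_variability",
                           "indeterminate")))
  expect_error(classify_risk(Inf, 1), "finite")
})
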