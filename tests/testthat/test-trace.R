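test_that("trace construction validates inputs and tracks missingness", {
  expect_error(glucose_trace(5, "2024-01-01"), "at least 2")
  expect_error(glucose_trace(c(5, -1, 6), "2024-01-01"), "non-positive")
  expect_error(glucose_trace(c(5, 6), "2024-01-01", interval = 0), "positive")
  tr <- glucose_trace(c(5, NA, 7), "2024-01-01 10:00:00")
  expect_equal(tr$missing_mask, c(FALSE, TRUE, FALSE))
  expect_equal(trace_completeness(tr), 2 / 3)
  expect_equal(as.numeric(diff(trace_times(tr)), units = "mins"), c(5, 5))
})

test_that("unit conversion is exact and round-trips", {
  tr <- glucose_trace(c(5.551, 10, 4.4), "2024-01-01")
  mg <- convert_units(tr, "mg_per_dl")
  expect_equal(mg$values, tr$values * 18.016)
  back <- convert_units(mg, "mmol_per_l")
  expect_equal(back$values, tr$values, tolerance = 1e-12)
  expect_identical(convert_units(tr, "mmol_per_l"), tr)
})

test_that("48-h window starts at the first midnight strictly after start", {
  v <- seq_len(72 * 12) / 100 + 5
  tr <- glucose_trace(v, "2024-03-01 10:00:00")
  win <- select_analysis_window(tr)
  expect_equal(length(win$values), 576)
  expect_equal(format(win$start, "%H:%M:%S"), "00:00:00")
  expect_equal(format(win$start, "%Y-%m-%d"), "2024-03-02")
  # samples are the contiguous slice starting at midnight
  i0 <- which(trace_times(tr) == win$start)
  expect_equal(win$values, v[i0:(i0 + 575)])

  # start exactly at midnight: the *following* midnight is used
  tr0 <- glucose_trace(v, "2024-03-01 00:00:00")
  win0 <- select_analysis_window(tr0)
  expect_equal(format(win0$start, "%Y-%m-%d %H:%M"), "2024-03-02 00:00")
})

test_that("window output length holds for any start time and interval", {
  set.seed(404)
  for (i in 1:20) {
    start <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") +
      round(runif(1, 0, 24 * 60 * 60 / 300)) * 300
    tr <- glucose_trace(runif(72 * 12, 4, 12), start)
    expect_equal(length(select_analysis_window(tr)$values), 576)
  }
  # non-5-min interval keeps window_hours * 60 / interval samples
  tr10 <- glucose_trace(runif(66 * 6, 4, 12), "2024-03-01 09:00:00",
                        interval = 10)
  expect_equal(length(select_analysis_window(tr10)$values), 288)
})

test_that("too-short recordings raise a window-not-coverable error", {
  tr <- glucose_trace(runif(40 * 12, 4, 12), "2024-03-01 10:00:00")
  expect_error(select_analysis_window(tr), "window not coverable")
  expect_error(select_analysis_window(tr), "short by")
})
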