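mk <- function(v, unit = "mmol_per_l", interval = 5)
  glucose_trace(v, "2024-03-01 00:00:00", interval = interval, unit = unit)

test_that("dispersion metrics reproduce hand-computed values", {
  tr <- mk(c(4, 6, 8, 6))
  expect_equal(glycaemic_sd(tr), sqrt(8 / 3))           # 1.63299...
  expect_equal(percent_cv(tr), 100 * sqrt(8 / 3) / 6)   # 27.2166
  expect_equal(glucose_range(tr), 4)
  expect_equal(interquartile_range(mk(1:8)), 3.5)       # type-7 interpolation
  expect_equal(glycaemic_sd(mk(rep(6, 10))), 0)
  expect_equal(percent_cv(mk(rep(6, 10))), 0)
  # mg/dl trace scales sd by 18.016, leaves %CV unchanged
  trmg <- mk(c(4, 6, 8, 6) * 18.016, unit = "mg_per_dl")
  expect_equal(glycaemic_sd(trmg), 18.016 * sqrt(8 / 3))
  expect_equal(percent_cv(trmg), percent_cv(tr))
})

test_that("J-index follows 0.001 x (mean + SD)^2 on mg/dl", {
  expect_equal(j_index(mk(rep(100, 10), unit = "mg_per_dl")), 10)
  expect_equal(j_index(mk(rep(100.01 / 18.016, 10))), 0.001 * 100.01^2)
  expect_gt(j_index(mk(c(4, 6, 8, 6))), 0)
})

test_that("M-value matches the closed form and is ratio-invariant", {
  expect_equal(m_value(mk(rep(5.6, 5)), R = 5.6), 0)
  expect_equal(m_value(mk(rep(11.2, 5)), R = 5.6), abs(10 * log10(2))^3)
  tr <- mk(c(4, 6, 8, 6))
  expect_equal(m_value(tr, R = 5.6),
               m_value(convert_units(tr, "mg_per_dl"), R = 5.6 * 18.016))
  # amplitude correction adds range/20 on mg/dl
  cfg <- metric_config(m_value_correction = TRUE)
  expect_equal(m_value(tr, R = 5.6, config = cfg),
               m_value(tr, R = 5.6) + 4 * 18.016 / 20)
})

test_that("IGC uses strict thresholds and the configured constants", {
  cfg <- metric_config()
  expect_equal(igc(mk(c(5, 6, 7, 7.7)), cfg)$igc, 0)      # in-range
  # exactly at the thresholds contributes zero
  expect_equal(igc(mk(c(4.4, 7.8)), cfg)$igc, 0)
  # direct evaluation at n = 2, values 200/60 mg/dl, thresholds 140/80 mg/dl
  cfg2 <- metric_config(hyper_threshold = 140 / 18.016,
                        hypo_threshold = 80 / 18.016)
  got <- igc(mk(c(200, 60), unit = "mg_per_dl"), cfg2)
  expect_equal(got$hyper_index, 60^1.1 / 60)
  expect_equal(got$hypo_index, 20^2 / 60)
  expect_equal(got$igc, got$hyper_index + got$hypo_index)
})

test_that("MAGE handles the canonical shapes", {
  expect_true(attr(mage(mk(rep(6, 576))), "no_excursion"))
  # sinusoid amplitude 3, period 3 h: MAGE = 2A within discretisation error
  t <- (0:575) * 5 / 60
  m_sin <- mage(mk(8 + 3 * sin(2 * pi * t / 3)))
  expect_equal(as.numeric(m_sin), 6, tolerance = 0.05)
  expect_equal(attr(m_sin, "n_excursions"), 16L)
  # single step: one boundary-to-boundary excursion of amplitude 7
  m_step <- mage(mk(c(rep(5, 288), rep(12, 288))))
  expect_equal(as.numeric(m_step), 7)
  expect_identical(attr(m_step, "direction"), "ascending")
  expect_error(mage(mk(c(5, 6))), "3 non-missing")
})

test_that("MAGE never falls below 1 SD when an excursion qualifies", {
  set.seed(99)
  for (i in 1:25) {
    tr <- random_trace(sample(60:600, 1))
    m <- mage(tr)
    if (!isTRUE(attr(m, "no_excursion")))
      expect_gt(as.numeric(m), glycaemic_sd(tr))
  }
})

test_that("MODD and CONGA satisfy their analytic limits", {
  t <- (0:575) * 5 / 60
  daily <- mk(8 + 2 * sin(2 * pi * t / 24))      # 24-h periodic
  expect_equal(modd(daily), 0, tolerance = 1e-12)
  shifted <- mk(c(8 + 2 * sin(2 * pi * t[1:288] / 24),
                  9 + 2 * sin(2 * pi * t[1:288] / 24)))
  expect_equal(modd(shifted), 1)                 # constant day-2 offset
  ramp <- mk(5 + 0.01 * (0:599))
  for (h in c(1, 3, 24)) expect_equal(conga_n(ramp, h), 0, tolerance = 1e-9)
  const <- mk(rep(7, 600))
  expect_equal(conga_n(const, 2), 0)
  expect_equal(conga_1_24(const), 0)
  expect_error(modd(mk(rep(6, 100))), "48 h")
  expect_error(conga_n(mk(rep(6, 10)), 24), "too short")
})

test_that("conga_1_24 is the mean of exactly 24 per-lag values", {
  tr <- random_trace(600, seed = 12)
  per_lag <- vapply(1:24, function(h) conga_n(tr, h), 0)
  expect_length(per_lag, 24)
  expect_equal(conga_1_24(tr), mean(per_lag))
})

test_that("metrics are scale-equivariant under mmol/l -> mg/dl", {
  tr <- random_trace(600, seed = 31)
  trmg <- convert_units(tr, "mg_per_dl")
  f <- 18.016
  expect_equal(glycaemic_sd(trmg), f * glycaemic_sd(tr))
  expect_equal(glucose_range(trmg), f * glucose_range(tr))
  expect_equal(interquartile_range(trmg), f * interquartile_range(tr))
  expect_equal(as.numeric(mage(trmg)), f * as.numeric(mage(tr)))
  expect_equal(modd(trmg), f * modd(tr))
  expect_equal(conga_n(trmg, 4), f * conga_n(tr, 4))
  expect_equal(percent_cv(trmg), percent_cv(tr))
  # J-index and IGC are unit-pinned (mg/dl), so identical either way
  expect_equal(j_index(trmg), j_index(tr))
  expect_equal(igc(trmg)$igc, igc(tr)$igc)
})

test_that("missing samples are excluded, pairs dropped for MODD/CONGA", {
  v <- rep(c(5, 7, 9, 7), 150)
  v[c(10, 100, 300)] <- NA
  tr <- mk(v)
  expect_equal(glycaemic_sd(tr), o_sd(v[!is.na(v)]))
  expect_equal(modd(tr), o_modd(v, 288))
  expect_equal(conga_n(tr, 2), o_conga(v, 24))
})

test_that("compute_profile aggregates and matches individual metrics", {
  tr <- random_trace(576, seed = 77)
  cfg <- metric_config()
  p <- compute_profile(tr, cfg, auto_window = FALSE)
  expect_equal(p$sd, glycaemic_sd(tr))
  expect_equal(p$iqr, interquartile_range(tr))
  expect_equal(p$j_index, j_index(tr, cfg))
  expect_equal(p$m_value, m_value(tr, config = cfg))
  expect_equal(p$modd, modd(tr))
  expect_equal(p$conga_1_24, conga_1_24(tr, cfg))
  expect_equal(p$igc, p$hyper_index + p$hypo_index)
  expect_equal(p$mage, as.numeric(mage(tr, cfg)))
  # constant trace: dispersion all zero, M-value zero at R
  cst <- mk(rep(5.6, 576))
  pc <- compute_profile(cst, cfg, auto_window = FALSE)
  expect_equal(pc$sd + pc$range + pc$iqr + pc$modd + pc$conga_1_24, 0)
  expect_equal(pc$m_value, 0)
  expect_true(is.na(pc$mage))
  # a raw 72-h recording is windowed automatically to 576 samples
  raw <- glucose_trace(runif(864, 4, 12), "2024-03-01 11:00:00")
  expect_equal(compute_profile(raw, cfg)$n_samples, 576)
})

test_that("profiles refuse incomplete traces below the completeness floor", {
  v <- runif(576, 4, 12)
  v[1:100] <- NA
  expect_error(compute_profile(mk(v), auto_window = FALSE), "completeness")
})
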