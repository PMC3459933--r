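test_that("a fixed seed reproduces the cohort bit-for-bit", {
  cfg <- generator_config(n_subjects = 5, seed = 123)
  a <- generate_cohort(cfg, profile = FALSE)
  b <- generate_cohort(cfg, profile = FALSE)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$traces, b$traces)
  c2 <- generate_cohort(generator_config(n_subjects = 5, seed = 124),
                        profile = FALSE)
  expect_false(identical(a$cohort$sd, c2$cohort$sd))
  expect_identical(names(a$cohort), names(c2$cohort))
})

test_that("degenerate limit: zero variability and noise give a flat trace", {
  cfg <- generator_config(n_subjects = 2, sensor_noise_sd = 0, seed = 1)
  tr <- simulate_trace(list(subject_id = "s", mu = 7.5, v = 0), cfg, seed = 4)
  expect_equal(unique(tr$values), 7.5)
  expect_equal(length(tr$values), 72 * 12)
})

test_that("traces respect the device range and the trace invariants", {
  cfg <- generator_config(n_subjects = 8, seed = 9)
  co <- generate_cohort(cfg, profile = FALSE)
  for (tr in co$traces) {
    expect_equal(length(tr$values), 576)
    expect_true(all(tr$values >= 2.2 & tr$values <= 22.2))
    expect_equal(trace_completeness(tr), 1)
    expect_equal(format(tr$start, "%H:%M"), "00:00")
  }
})

test_that("latent variability drives the realised glycaemic SD", {
  co <- generate_cohort(generator_config(n_subjects = 200, seed = 21),
                        profile = FALSE)
  expect_gt(cor(co$latent$v, co$cohort$sd), 0.8)
})

test_that("lab couplings run in the documented directions", {
  cfg <- generator_config(n_subjects = 2, seed = 1)
  base <- list(subject_id = "s", mu = 9.5, type = "type2", b = 0.42)
  tr <- simulate_trace(c(base, v = 2), cfg, seed = 7)
  # expected GA/A1c ratio strictly increases with v at fixed chronic mean
  labs_lo <- simulate_labs(c(base, v = 1.0), tr, cfg, seed = 11)
  labs_hi <- simulate_labs(c(base, v = 4.5), tr, cfg, seed = 11)
  expect_gt(labs_hi$ga_percent / labs_hi$hba1c_value,
            labs_lo$ga_percent / labs_lo$hba1c_value)
  # extreme variability in type 1 floors FCPR at the detection limit
  b1 <- list(subject_id = "s", mu = 9.5, type = "type1", b = 1e-5)
  labs1 <- simulate_labs(c(b1, v = 8), tr, cfg, seed = 13)
  expect_equal(labs1$fcpr, 0.001)
  expect_true(labs1$fcpr_below_limit)
})

test_that("cohort marginals approach the configured targets", {
  co <- generate_cohort(generator_config(n_subjects = 400, seed = 33),
                        profile = FALSE)
  d <- co$cohort
  expect_equal(mean(d$sd), 3.0, tolerance = 0.15)
  expect_equal(mean(d$mean_glucose), 9.5, tolerance = 0.1)
  expect_equal(mean(d$ga_a1c_ratio), 2.9, tolerance = 0.1)
  expect_equal(sum(d$type == "type1") / nrow(d), 0.44, tolerance = 0.01)
  expect_gt(mean(d$sd[d$type == "type1"]), mean(d$sd[d$type == "type2"]))
})

test_that("zero couplings remove the index-variability association", {
  cfg <- generator_config(n_subjects = 150, seed = 55,
                          coupling_ga = 0, coupling_fcpr = 0,
                          sd_target_type1 = c(mean = 3.0, sd = 1.1),
                          sd_target_type2 = c(mean = 3.0, sd = 1.1))
  d <- generate_cohort(cfg, profile = FALSE)$cohort
  expect_lt(abs(cor(d$sd, d$ga_a1c_ratio)), 0.2)
  expect_lt(abs(cor(d$sd, rank(d$fcpr_index))), 0.2)
})

test_that("the optional gap model injects missingness", {
  cfg <- generator_config(n_subjects = 2, seed = 66, gap_rate = 3)
  tr <- simulate_trace(list(subject_id = "s", mu = 9, v = 2), cfg, seed = 8)
  expect_gt(sum(tr$missing_mask), 0)
  expect_lt(trace_completeness(tr), 1)
})
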