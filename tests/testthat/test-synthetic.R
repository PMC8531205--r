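# Synthetic generators: determinism, exact zero-noise structure, and the
# documented study-design defaults.

test_that("gen_cohort honours zero variance, determinism and the LLN", {
  co <- gen_cohort("T18", 9, mass_mean_g = 1.3, mass_sd_g = 0)
  expect_equal(nrow(co), 9)
  expect_true(all(co$mass_g == 1.3))

  a <- gen_cohort("T25", 10, 0.7, 0.07, seed = 42)
  b <- gen_cohort("T25", 10, 0.7, 0.07, seed = 42)
  expect_identical(a, b)

  big <- gen_cohort("T25", 10000, 0.7, 0.07 * sqrt(10), seed = 7)
  expect_lt(abs(mean(big$mass_g) - 0.7) / 0.7, 0.01)
  expect_true(all(big$mass_g > 0))

  expect_error(gen_cohort("T18", 0, 1.3, 0.1), "positive integer")
})

test_that("zero-noise O2 traces invert exactly through a slope fit", {
  m <- 4.2  # umol O2 / g / h
  tr <- gen_o2_trace(m, mass_g = 1.0, chamber_ml = 43, temp_C = 25,
                     n_cycles = 2, seal_min = 8, noise_sd_pct = 0)
  v_re <- (43 - 1.0) / 1000
  segs <- segment_cycles(tr, dead_time_s = 0)
  for (seg in segs) {
    sl <- fit_slope(seg)
    expect_equal(sl$slope_umol_L_h, -m * 1.0 / v_re, tolerance = 1e-9)
    expect_equal(sl$r2, 1)
  }
})

test_that("a zero-rate trace holds sealed-phase saturation constant", {
  tr <- gen_o2_trace(0, mass_g = 1, temp_C = 25, noise_sd_pct = 0,
                     background_umol_h = 0)
  sealed <- tr[tr$phase == "seal", ]
  expect_true(all(abs(sealed$sat_pct - 100) < 1e-12))
})

test_that("traces crossing the saturation floor are rejected by cycle", {
  expect_error(
    gen_o2_trace(40, mass_g = 1.3, chamber_ml = 43, temp_C = 34,
                 seal_min = 20),
    "cycle 1")
})

test_that("O2 trace generation is deterministic under a fixed seed", {
  a <- gen_o2_trace(5, 1, noise_sd_pct = 1, seed = 11)
  b <- gen_o2_trace(5, 1, noise_sd_pct = 1, seed = 11)
  expect_identical(a$sat_pct, b$sat_pct)
})

test_that("heart-signal beat counts and sample counts follow the design", {
  rec <- gen_heart_signal(60, duration_s = 300, fs_hz = 1000, beat_cv = 0,
                          noise_sd = 0)
  expect_equal(length(rec$voltage), 300 * 1000)
  # one beat per second; the boundary beat may fall either side
  expect_true(abs(length(rec$beat_times_s) - 300) <= 1)
  expect_error(gen_heart_signal(60, beat_cv = -0.1), "non-negative")
  expect_error(gen_heart_signal(60, duration_s = 30), ">= 60")
  expect_error(gen_heart_signal(60, fs_hz = 50), ">= 100")
})

test_that("ramp events land at the exact linear-ramp arithmetic", {
  r1 <- gen_ctmax_ramp(18, 0.1, 36.8)
  expect_equal(attr(r1, "event_time_min"), 188, tolerance = 1e-8)
  r2 <- gen_ctmax_ramp(25, 0.1, 36.7)
  expect_equal(attr(r2, "event_time_min"), 117, tolerance = 1e-8)
  # noiseless regression slope equals the configured rate exactly
  expect_equal(estimate_heating_rate(r1), 0.1, tolerance = 1e-10)
  expect_error(gen_ctmax_ramp(18, 0, 36.8), "positive")
  expect_error(gen_ctmax_ramp(18, 0.1, 17), "exceed")
})

test_that("habitat generator produces exact extremes at zero noise", {
  flat <- gen_habitat_series("2019-01-01", "2019-01-10", daily_mean_C = 21.9,
                             daily_amplitude_C = 0, seasonal_amplitude_C = 0,
                             noise_sd = 0)
  ds <- daily_stats(flat)
  expect_true(all(ds$tmin_C == 21.9 & ds$tmax_C == 21.9 &
                  ds$tmean_C == 21.9))

  diel <- gen_habitat_series("2019-03-01", "2019-03-07",
                             daily_amplitude_C = 2,
                             seasonal_amplitude_C = 0, noise_sd = 0)
  dd <- daily_stats(diel)
  expect_true(all(abs((dd$tmax_C - dd$tmin_C) - 4) < 1e-12))

  yr <- gen_habitat_series("2019-01-01", "2019-12-31", noise_sd = 0)
  expect_true(abs(nrow(yr) - 8760) <= 24)
  expect_error(gen_habitat_series("2019-06-01", "2019-01-01"), "after")
})

test_that("condition defaults carry the reported means and flag the rest", {
  cd <- condition_defaults()
  pick <- function(g, k, t) cd[cd$group == g & cd$kind == k &
                               cd$test_temp_C == t, ]
  expect_equal(pick("T25", "routine", 30)$mo2_umol_g_h, 15.95)
  expect_equal(pick("T25", "routine", 30)$source, "reported")
  expect_equal(pick("T18", "maximum", 25)$mo2_umol_g_h, 20.2)
  expect_equal(pick("T18", "routine", 34)$mo2_umol_g_h, 7.44)
  expect_equal(pick("T18", "routine", 20)$source, "interpolated")
  # interpolated values follow Q10 = 2 from their anchor
  expect_equal(pick("T18", "routine", 20)$mo2_umol_g_h,
               5.37 * 2^((20 - 30) / 10))
  # all T25 maximum rows are non-empirical
  expect_true(all(cd$source[cd$group == "T25" & cd$kind == "maximum"] ==
                  "interpolated"))
  hd <- heart_rate_defaults()
  expect_equal(hd$fh_bpm[hd$test_temp_C == 18 & hd$condition == "routine"],
               52.07)
  expect_equal(hd$fh_bpm[hd$test_temp_C == 25 & hd$condition == "atropine"],
               98.1)
})

test_that("generators are statistically unbiased at moderate noise", {
  # respirometry estimate over replicates centres on truth
  truth <- 10
  est <- vapply(1:60, function(i) {
    tr <- gen_o2_trace(truth, mass_g = 1, temp_C = 25, seal_min = 8,
                       noise_sd_pct = 0.5, seed = i)
    mo2_from_trace(tr)$mo2_mass_specific_umol_g_h
  }, 1)
  est <- est[!is.na(est)]
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 2 * mc_se + 1e-6)
})
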