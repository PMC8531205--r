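# Intermittent-flow respirometry: segmentation, slope fitting, QC and the
# effective-volume metabolic-rate equation.

test_that("segment_cycles extracts sealed phases and trims dead time", {
  tr <- gen_o2_trace(2, mass_g = 1, n_cycles = 2, seal_min = 10,
                     flush_min = 5, fs_hz = 0.2)
  segs <- segment_cycles(tr, dead_time_s = 0)
  expect_length(segs, 2)

  # 60 s dead time at 0.2 Hz drops the first 12 samples of each segment
  trimmed <- segment_cycles(tr, dead_time_s = 60)
  expect_equal(nrow(segs[[1]]) - nrow(trimmed[[1]]), 12)

  all_flush <- tr
  all_flush$phase <- "flush"
  expect_error(segment_cycles(all_flush), "no sealed")
})

test_that("fit_slope reproduces an exact concentration line", {
  t_h <- seq(0, 0.5, by = 1 / 720)
  seg <- segment_from_conc(t_h, 250 - 50 * t_h)
  sl <- fit_slope(seg)
  expect_equal(sl$slope_umol_L_h, -50, tolerance = 1e-9)
  expect_equal(sl$r2, 1)
})

test_that("a flat segment has slope 0 and r2 defined as 0", {
  seg <- segment_from_conc(seq(0, 0.5, by = 0.01), rep(200, 51))
  sl <- fit_slope(seg)
  expect_equal(sl$slope_umol_L_h, 0)
  expect_equal(sl$r2, 0)
})

test_that("fit_slope agrees with a normal-equations oracle on noisy data", {
  set.seed(99)
  t_h <- seq(0, 0.4, by = 0.005)
  conc <- 240 - 80 * t_h + rnorm(length(t_h), 0, 2)
  seg <- segment_from_conc(t_h, conc)
  sl <- fit_slope(seg)
  orc <- ols_oracle(t_h, sat_to_conc(seg$sat_pct, seg$temp_C))
  expect_equal(sl$slope_umol_L_h, orc$slope, tolerance = 1e-9)
})

test_that("fit_slope input contracts are enforced", {
  seg <- segment_from_conc(seq(0, 0.05, by = 0.01), 200 - 1:6)
  expect_error(fit_slope(seg), "at least 10")
  seg2 <- segment_from_conc(rep(0.1, 12), 200 + 1:12)
  expect_error(fit_slope(seg2), "degenerate")
})

test_that("QC boundaries are inclusive and rejections carry reasons", {
  mk <- function(r2, smin) {
    structure(list(cycle_index = 1L, slope_umol_L_h = -10, r2 = r2,
                   sat_min_pct = smin, sat_max_pct = 100, n_points = 50),
              class = "slope_estimate")
  }
  out <- qc_filter(list(mk(0.94, 95), mk(0.95, 80.0), mk(0.99, 79)))
  expect_length(out$passed, 1)
  expect_equal(out$passed[[1]]$r2, 0.95)
  expect_equal(out$rejected[[1]]$reasons, "low_r2")
  expect_equal(out$rejected[[2]]$reasons, "sat_floor")
})

test_that("compute_mo2 applies the effective-volume equation", {
  sl <- structure(list(cycle_index = 1L, slope_umol_L_h = -100, r2 = 1,
                       sat_min_pct = 90, sat_max_pct = 100, n_points = 100),
                  class = "slope_estimate")
  e1 <- compute_mo2(sl, chamber_ml = 43, mass_g = 1.0)
  expect_equal(e1$v_re_L, 0.042)
  expect_equal(e1$mo2_total_umol_h, 4.2)
  expect_equal(e1$mo2_mass_specific_umol_g_h, 4.2)

  e2 <- compute_mo2(sl, chamber_ml = 43, mass_g = 0.7)
  expect_equal(e2$v_re_L, 0.0423)
  expect_equal(e2$mo2_mass_specific_umol_g_h, 6.042857142857, tolerance = 1e-9)

  # background equal to the uncorrected rate zeroes the estimate
  e3 <- compute_mo2(sl, 43, 1.0, background_umol_h = 4.2)
  expect_equal(e3$mo2_total_umol_h, 0)

  # over-subtraction flags rather than clips
  e4 <- compute_mo2(sl, 43, 1.0, background_umol_h = 5)
  expect_lt(e4$mo2_total_umol_h, 0)
  expect_false(e4$qc_passed)

  expect_error(compute_mo2(sl, 43, 0), "positive")
  expect_error(compute_mo2(sl, 1, 1.3), "exceed")
})

test_that("duplicate summaries average survivors and report losses", {
  mk <- function(total, ms) {
    structure(list(mo2_total_umol_h = total,
                   mo2_mass_specific_umol_g_h = ms, qc_passed = TRUE),
              class = "metabolic_estimate")
  }
  s <- summarize_duplicates(list(mk(4.0, 4.0), mk(4.4, 4.4)))
  expect_equal(s$mo2_mass_specific_umol_g_h, 4.2)
  expect_equal(s$n_used, 2L)

  s1 <- summarize_duplicates(list(mk(5.0, 5.0)))
  expect_equal(s1$mo2_mass_specific_umol_g_h, 5.0)
  expect_equal(s1$n_used, 1L)

  s0 <- summarize_duplicates(list(), reasons = c("low_r2", "sat_floor"))
  expect_true(is.na(s0$mo2_mass_specific_umol_g_h))
  expect_equal(s0$n_used, 0L)
  expect_setequal(s0$reasons, c("low_r2", "sat_floor"))
})

test_that("the full pipeline inverts zero-noise traces to <= 0.1%", {
  for (temp in c(15, 20, 25, 30, 34)) {
    tr <- gen_o2_trace(8, mass_g = 0.9, temp_C = temp, seal_min = 5,
                       noise_sd_pct = 0)
    est <- mo2_from_trace(tr)
    expect_lt(abs(est$mo2_mass_specific_umol_g_h - 8) / 8, 0.001)
  }
})

test_that("MO2 is linear in slope and in effective volume", {
  mk <- function(slope) {
    structure(list(cycle_index = 1L, slope_umol_L_h = slope, r2 = 1,
                   sat_min_pct = 90, sat_max_pct = 100, n_points = 50),
              class = "slope_estimate")
  }
  base <- compute_mo2(mk(-50), 43, 1)$mo2_total_umol_h
  expect_equal(compute_mo2(mk(-100), 43, 1)$mo2_total_umol_h, 2 * base)
  # doubling V_RE at fixed slope doubles the total
  v1 <- compute_mo2(mk(-50), 43, 1)$mo2_total_umol_h
  v2 <- compute_mo2(mk(-50), 85, 1)$mo2_total_umol_h
  expect_equal(v2 / v1, (85 - 1) / (43 - 1), tolerance = 1e-12)
})

test_that("background subtraction distributes over mass normalization", {
  sl <- structure(list(cycle_index = 1L, slope_umol_L_h = -80, r2 = 1,
                       sat_min_pct = 85, sat_max_pct = 100, n_points = 50),
                  class = "slope_estimate")
  mass <- 0.8; bg <- 0.5
  a <- compute_mo2(sl, 43, mass, background_umol_h = bg)
  b <- compute_mo2(sl, 43, mass, background_umol_h = 0)
  expect_equal(a$mo2_mass_specific_umol_g_h,
               b$mo2_mass_specific_umol_g_h - bg / mass, tolerance = 1e-12)
})

test_that("median recovery at 1% saturation noise stays within 5%", {
  truth <- 12
  seal <- auto_seal_min(truth, 1, 43, 25)
  est <- vapply(1:100, function(i) {
    tr <- gen_o2_trace(truth, mass_g = 1, temp_C = 25, seal_min = seal,
                       noise_sd_pct = 1, seed = 1000 + i)
    mo2_from_trace(tr)$mo2_mass_specific_umol_g_h
  }, 1)
  # QC legitimately drops some noisy cycles; the survivors carry the answer
  expect_gt(mean(!is.na(est)), 0.5)
  expect_lt(abs(median(est, na.rm = TRUE) - truth) / truth, 0.05)
})
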