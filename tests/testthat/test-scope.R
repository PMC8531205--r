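# Aerobic scope curves, Gaussian thermal performance fits and Q10.

test_that("scope curves compute AAS and FAS on group means", {
  temps <- c(15, 20, 25, 30, 34)
  r <- data.frame(test_temp_C = rep(temps, 2), mo2 = rep(c(2, 3, 4, 5, 6), 2))
  m <- data.frame(test_temp_C = rep(temps, 2),
                  mo2 = rep(c(8, 12, 16, 18, 17), 2))
  sc <- build_scope_curve(r, m, group = "T18")
  expect_equal(sc$aas, c(6, 9, 12, 13, 11))
  expect_equal(sc$fas, c(4, 4, 4, 3.6, 17 / 6))

  # equal rates: AAS 0, FAS 1
  eq <- build_scope_curve(r, r)
  expect_true(all(eq$aas == 0) && all(eq$fas == 1))

  # printed means at the warmest tested condition
  one <- build_scope_curve(
    data.frame(test_temp_C = c(25, 34), mo2 = c(3.8, 7.44)),
    data.frame(test_temp_C = c(25, 34), mo2 = c(20.2, 23.6)))
  expect_equal(one$aas[one$test_temp_C == 34], 16.16)
  expect_equal(one$fas[one$test_temp_C == 34], 3.17, tolerance = 0.002)
})

test_that("zero routine rate yields missing FAS but defined AAS", {
  r <- data.frame(test_temp_C = c(15, 20, 25), mo2 = c(0, 2, 3))
  m <- data.frame(test_temp_C = c(15, 20, 25), mo2 = c(5, 6, 7))
  sc <- build_scope_curve(r, m)
  expect_true(is.na(sc$fas[sc$test_temp_C == 15]))
  expect_equal(sc$aas[sc$test_temp_C == 15], 5)
})

test_that("non-overlapping temperatures are an error", {
  r <- data.frame(test_temp_C = c(15, 20), mo2 = c(1, 2))
  m <- data.frame(test_temp_C = c(30, 34), mo2 = c(5, 6))
  expect_error(build_scope_curve(r, m), "at least 2 test temperatures")
})

test_that("FAS = 1 + AAS / rMO2 wherever rMO2 > 0", {
  set.seed(6)
  temps <- c(15, 20, 25, 30, 34)
  r <- data.frame(test_temp_C = temps, mo2 = runif(5, 1, 8))
  m <- data.frame(test_temp_C = temps, mo2 = runif(5, 8, 25))
  sc <- build_scope_curve(r, m)
  expect_equal(sc$fas, 1 + sc$aas / sc$rmo2_mean, tolerance = 1e-12)
})

test_that("noise-free Gaussians are recovered to machine-level accuracy", {
  temps <- c(15, 20, 25, 30, 34)
  y <- 16 * exp(-(temps - 27)^2 / (2 * 36))
  fit <- fit_gaussian_tpc(temps, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$amplitude - 16) / 16, 1e-6)
  expect_lt(abs(fit$t_opt_C - 27) / 27, 1e-6)
  expect_lt(abs(fit$breadth_C - 6) / 6, 1e-6)
  expect_false(fit$boundary)

  withb <- fit_gaussian_tpc(temps, y + 2, with_baseline = TRUE)
  expect_lt(abs(withb$baseline - 2), 1e-4)
  expect_lt(abs(withb$t_opt_C - 27), 1e-4)
})

test_that("monotone data pin the optimum at the boundary and are flagged", {
  temps <- c(15, 20, 25, 30, 34)
  fit <- fit_gaussian_tpc(temps, c(1, 2, 4, 8, 16))
  expect_true(fit$boundary)
  expect_gte(fit$t_opt_C, 34)
})

test_that("underdetermined fits are rejected", {
  expect_error(fit_gaussian_tpc(c(15, 20, 25), c(1, 2, 1)), "at least 4")
  expect_error(fit_gaussian_tpc(c(15, 20, 25, 30), c(1, 2, 2, 1),
                                with_baseline = TRUE), "at least 5")
})

test_that("multi-start never loses to the best single grid start", {
  set.seed(12)
  temps <- c(15, 20, 25, 30, 34)
  y <- 10 * exp(-(temps - 22)^2 / (2 * 25)) + rnorm(5, 0, 0.4)
  fit <- fit_gaussian_tpc(temps, y)
  pred <- fit$amplitude * exp(-(temps - fit$t_opt_C)^2 / (2 * fit$breadth_C^2))
  expect_equal(fit$rss, sum((y - pred)^2), tolerance = 1e-8)
  # residual never exceeds the flat-model baseline
  expect_lte(fit$rss, sum((y - mean(y))^2))
})

test_that("q10 reproduces worked values and composes multiplicatively", {
  # heart-rate means at 18 and 25 degC: rounds to the printed 1.9
  q <- q10(52.07, 80.3, 18, 25)
  expect_equal(q$q10, 1.86, tolerance = 0.005)
  expect_equal(round(q$q10, 1), 1.9)

  expect_equal(q10(10, 20, 15, 25)$q10, 2.0)
  expect_equal(q10(7, 7, 12, 31)$q10, 1.0)

  set.seed(8)
  for (i in 1:20) {
    r <- runif(3, 1, 50)
    t <- sort(runif(3, 5, 40))
    lhs <- q10(r[1], r[2], t[1], t[2])$q10 ^ ((t[2] - t[1]) / 10) *
           q10(r[2], r[3], t[2], t[3])$q10 ^ ((t[3] - t[2]) / 10)
    rhs <- q10(r[1], r[3], t[1], t[3])$q10 ^ ((t[3] - t[1]) / 10)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }

  expect_error(q10(0, 5, 10, 20), "positive")
  expect_error(q10(5, 5, 20, 20), "differ")
})
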