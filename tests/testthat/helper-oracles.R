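# Independent brute-force oracles, kept free of the package's code paths.

withr_tempdir <- function() {
  d <- tempfile("tadscope-test-")
  dir.create(d)
  d
}

# OLS slope/intercept by explicit normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept,
       residuals = y - intercept - slope * x)
}

# Welch t statistic by the textbook formula
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exhaustive minimum-CV window search over beat times (fine stride)
best_window_oracle <- function(times, window_s, stride = 0.25) {
  starts <- seq(times[1], times[length(times)] - window_s, by = stride)
  best <- list(cv = Inf)
  for (s in starts) {
    w <- times[times >= s & times <= s + window_s]
    if (length(w) < 3) next
    ibi <- diff(w)
    cv <- sd(ibi) / mean(ibi)
    if (cv < best$cv) {
      best <- list(cv = cv,
                   fh = 60 * (length(w) - 1) / (w[length(w)] - w[1]))
    }
  }
  best
}

# build a sealed-segment data.frame directly from a concentration line,
# inverting the solubility model so fit_slope sees an exact line
segment_from_conc <- function(time_h, conc_umol_l, temp_C = 25) {
  csat <- tadscope::o2_solubility_umol_l(temp_C)
  data.frame(time_h = time_h, sat_pct = conc_umol_l / csat * 100,
             temp_C = temp_C, phase = "seal")
}
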