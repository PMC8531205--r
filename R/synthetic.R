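#' Default condition table: mass-specific metabolic rates and heart rates
#'
#' Group-by-temperature defaults used by the synthetic generators. Values
#' with `source == "reported"` are group means printed in the source study's
#' results (two acclimation groups, T18 and T25, named for their holding
#' temperatures). Where a condition was not printed, the value is filled on
#' a log-linear temperature curve: interpolation between reported anchors
#' when they bracket the test temperature, otherwise extrapolation from the
#' nearest anchor at Q10 = 2; those rows carry `source == "interpolated"`
#' and should not be treated as empirical.
#'
#' @return data.frame with columns `group`, `test_temp_C`, `kind`
#'   (routine/maximum), `mo2_umol_g_h` (mass-specific metabolic rate) and
#'   `source`
#' @seealso [heart_rate_defaults()], [ctmax_defaults()], [cohort_defaults()]
#' @export
condition_defaults <- function() {
  temps <- c(15, 20, 25, 30, 34)
  q10_fill <- function(anchor_temp, anchor_val, t) {
    anchor_val * 2^((t - anchor_temp) / 10)
  }
  loglin <- function(t1, v1, t2, v2, t) {
    exp(log(v1) + (log(v2) - log(v1)) * (t - t1) / (t2 - t1))
  }
  rows <- list()
  add <- function(group, kind, temp, val, src) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, test_temp_C = temp, kind = kind,
      mo2_umol_g_h = val, source = src, stringsAsFactors = FALSE)
  }
  # routine, T18: reported at 30 and 34 degC
  add("T18", "routine", 30, 5.37, "reported")
  add("T18", "routine", 34, 7.44, "reported")
  for (t in c(15, 20, 25)) add("T18", "routine", t, q10_fill(30, 5.37, t), "interpolated")
  # routine, T25: reported at 30 and 34 degC
  add("T25", "routine", 30, 15.95, "reported")
  add("T25", "routine", 34, 16.01, "reported")
  for (t in c(15, 20, 25)) add("T25", "routine", t, q10_fill(30, 15.95, t), "interpolated")
  # maximum, T18: reported at 25 and ~34 degC; 30 bracketed by anchors
  add("T18", "maximum", 25, 20.2, "reported")
  add("T18", "maximum", 34, 23.6, "reported")
  add("T18", "maximum", 30, loglin(25, 20.2, 34, 23.6, 30), "interpolated")
  for (t in c(15, 20)) add("T18", "maximum", t, q10_fill(25, 20.2, t), "interpolated")
  # maximum, T25: no group means printed; the study reports only that the
  # curve stayed below T18's. We place it at 75% of the T18 curve.
  t18max <- do.call(rbind, rows)
  t18max <- t18max[t18max$group == "T18" & t18max$kind == "maximum", ]
  for (t in temps) {
    v <- 0.75 * t18max$mo2_umol_g_h[t18max$test_temp_C == t]
    add("T25", "maximum", t, v, "interpolated")
  }
  out <- do.call(rbind, rows)
  out[order(out$group, out$kind, out$test_temp_C), , drop = FALSE]
}

#' Default heart-rate condition table
#'
#' Routine, post-atropine and double-blockade (atropine + sotalol) heart
#' rates at the two test temperatures, transcribed from the source study's
#' printed group means (beats per minute).
#'
#' @return data.frame with columns `test_temp_C`, `condition`, `fh_bpm`
#' @export
heart_rate_defaults <- function() {
  data.frame(
    test_temp_C = rep(c(18, 25), each = 3),
    condition = rep(c("routine", "atropine", "double"), 2),
    fh_bpm = c(52.07, 59.5, 54.4, 80.3, 98.1, 85.5),
    stringsAsFactors = FALSE
  )
}

#' Default thermal-tolerance parameters per acclimation group
#'
#' Critical thermal maxima (mean and s.e.m.), realized protocol heating
#' slopes and sample sizes per acclimation group, as printed in the source
#' study's results.
#'
#' @return data.frame with columns `group`, `ctmax_C`, `ctmax_sem_C`, `n`,
#'   `heating_rate_C_min`, `start_C`
#' @export
ctmax_defaults <- function() {
  data.frame(
    group = c("T18", "T25"),
    ctmax_C = c(36.8, 36.7),
    ctmax_sem_C = c(0.2, 0.09),
    n = c(7L, 8L),
    heating_rate_C_min = c(0.089, 0.091),
    start_C = c(18, 25),
    stringsAsFactors = FALSE
  )
}

#' Default cohort biometrics per acclimation group
#'
#' Body-size means and s.e.m. per acclimation group (total length TL,
#' partial length PL, body width BW in mm; body mass in g).
#'
#' @return data.frame of group-level biometric means/s.e.m. and n
#' @export
cohort_defaults <- function() {
  data.frame(
    group = c("T18", "T25"),
    n = c(9L, 10L),
    mass_mean_g = c(1.3, 0.7), mass_sem_g = c(0.1, 0.07),
    tl_mean_mm = c(54.7, 46.7), tl_sem_mm = c(1.5, 1.3),
    pl_mean_mm = c(17.9, 14.8), pl_sem_mm = c(0.6, 0.3),
    bw_mean_mm = c(9.9, 7.6), bw_sem_mm = c(0.5, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort of animals
#'
#' Draws per-animal biometrics from normal laws truncated at zero
#' (redrawing non-positive values), reproducible under a fixed seed.
#'
#' @param group acclimation label, e.g. "T18"
#' @param n number of animals (>= 1)
#' @param mass_mean_g,mass_sd_g body-mass mean and between-animal sd, grams
#' @param tl_mean_mm,pl_mean_mm,bw_mm length/width means, millimetres
#' @param length_cv coefficient of variation applied to the three linear
#'   measures (between-animal variance is not reported per animal in the
#'   source study, so it is a free parameter)
#' @param seed integer RNG seed
#' @return data.frame with one row per animal: `animal_id`, `group`,
#'   `mass_g`, `tl_mm`, `pl_mm`, `bw_mm`
#' @export
gen_cohort <- function(group, n, mass_mean_g, mass_sd_g,
                       tl_mean_mm = 50, pl_mean_mm = 16, bw_mm = 9,
                       length_cv = 0.08, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  stopifnot(mass_mean_g > 0, mass_sd_g >= 0, tl_mean_mm > 0,
            pl_mean_mm > 0, bw_mm > 0)
  rng <- local_rng(seed)
  rtruncpos <- function(k, mean, sd) {
    if (sd == 0) return(rep(mean, k))
    x <- stats::rnorm(k, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  data.frame(
    animal_id = sprintf("%s_%02d", group, seq_len(n)),
    group = group,
    mass_g = rtruncpos(n, mass_mean_g, mass_sd_g),
    tl_mm = rtruncpos(n, tl_mean_mm, tl_mean_mm * length_cv),
    pl_mm = rtruncpos(n, pl_mean_mm, pl_mean_mm * length_cv),
    bw_mm = rtruncpos(n, bw_mm, bw_mm * length_cv),
    stringsAsFactors = FALSE
  )
}

# One seeded stream per generator call: each generator seeds the session
# RNG once at entry, so identical seed + parameters give identical output.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Generate a synthetic intermittent-flow respirometry trace
#'
#' Simulates alternating flush and sealed phases in a closed respirometer.
#' During sealed phases, percent air saturation declines at the rate implied
#' by the organism's oxygen consumption plus any background (microbial)
#' consumption, acting on the effective water volume (chamber volume minus
#' organism volume at density 1 kg per litre), converted to percent units
#' through the freshwater solubility model. Flush phases restore saturation
#' exponentially toward 100% with a 30 s time constant. Gaussian noise is
#' added to the saturation channel (the sensor's native unit).
#'
#' @param true_mo2_umol_g_h ground-truth mass-specific oxygen consumption,
#'   umol O2 per g per h
#' @param mass_g organism wet mass, g
#' @param chamber_ml total respirometer volume, mL (default 43)
#' @param temp_C test temperature, degC
#' @param n_cycles number of sealed measurement cycles (default 2,
#'   duplicate determinations)
#' @param seal_min,flush_min sealed and flush phase durations, minutes
#' @param fs_hz sampling rate of the oxygen sensor, Hz (default 0.2)
#' @param noise_sd_pct sd of Gaussian noise on the saturation channel,
#'   percentage points
#' @param background_umol_h background (control) oxygen consumption, umol/h
#' @param sat_floor_pct lowest saturation the protocol tolerates within a
#'   sealed phase (default 80); parameter combinations that would cross the
#'   floor are rejected with an error naming the cycle
#' @param trial_kind "routine" or "maximum"
#' @param group,animal_id metadata carried on the trace
#' @param pressure_kPa barometric pressure, kPa
#' @param seed integer RNG seed
#' @return an `o2_trace` object: data.frame (`time_h`, `sat_pct`, `temp_C`,
#'   `phase`, `cycle`) with chamber/mass/trial metadata attributes
#' @export
gen_o2_trace <- function(true_mo2_umol_g_h, mass_g, chamber_ml = 43,
                         temp_C = 25, n_cycles = 2, seal_min = 10,
                         flush_min = 5, fs_hz = 0.2, noise_sd_pct = 0,
                         background_umol_h = 0, sat_floor_pct = 80,
                         trial_kind = "routine", group = NA_character_,
                         animal_id = NA_character_,
                         pressure_kPa = 101.325, seed = 1L) {
  stopifnot(true_mo2_umol_g_h >= 0, mass_g > 0, n_cycles >= 1,
            seal_min > 0, flush_min > 0, fs_hz > 0)
  if (chamber_ml <= mass_g) {
    stop("chamber volume must exceed the organism's displacement volume")
  }
  v_re_L <- (chamber_ml - mass_g) / 1000
  c_sat <- o2_solubility_umol_l(temp_C, pressure_kPa)
  # saturation decline rate during a seal, percentage points per hour
  decline_pct_h <- (true_mo2_umol_g_h * mass_g + background_umol_h) /
    v_re_L / c_sat * 100
  end_sat <- 100 - decline_pct_h * seal_min / 60
  if (end_sat < sat_floor_pct) {
    stop(sprintf(
      "cycle 1: saturation would fall to %.1f%% (< floor %.1f%%); shorten seal_min or reduce the rate",
      end_sat, sat_floor_pct))
  }
  rng <- local_rng(seed)
  dt_s <- 1 / fs_hz
  seal_n <- ceiling(seal_min * 60 * fs_hz)
  flush_n <- ceiling(flush_min * 60 * fs_hz)
  tau_s <- 30  # flush reoxygenation time constant

  time_s <- numeric(0); sat <- numeric(0); phase <- character(0)
  cycle <- integer(0)
  t0 <- 0; s0 <- 100
  for (cy in seq_len(n_cycles)) {
    ts <- t0 + seq_len(seal_n) * dt_s - dt_s
    ss <- s0 - decline_pct_h * (ts - t0) / 3600
    time_s <- c(time_s, ts); sat <- c(sat, ss)
    phase <- c(phase, rep("seal", seal_n)); cycle <- c(cycle, rep(cy, seal_n))
    t0 <- t0 + seal_n * dt_s; s_end <- ss[length(ss)]
    tf <- t0 + seq_len(flush_n) * dt_s - dt_s
    sf <- 100 - (100 - s_end) * exp(-(tf - t0) / tau_s)
    time_s <- c(time_s, tf); sat <- c(sat, sf)
    phase <- c(phase, rep("flush", flush_n)); cycle <- c(cycle, rep(cy, flush_n))
    t0 <- t0 + flush_n * dt_s
    s0 <- sf[length(sf)]
  }
  if (noise_sd_pct > 0) sat <- sat + stats::rnorm(length(sat), 0, noise_sd_pct)

  out <- data.frame(time_h = time_s / 3600, sat_pct = sat, temp_C = temp_C,
                    phase = phase, cycle = cycle, stringsAsFactors = FALSE)
  structure(out,
            chamber_ml = chamber_ml, mass_g = mass_g,
            trial_kind = trial_kind, group = group, animal_id = animal_id,
            pressure_kPa = pressure_kPa,
            true_mo2_umol_g_h = true_mo2_umol_g_h,
            background_umol_h = background_umol_h,
            class = c("o2_trace", "data.frame"))
}

#' Generate a synthetic heart-electrode recording
#'
#' Beat times are laid down with inter-beat intervals
#' `60/true_fh_bpm * (1 + beat_cv * eps)`, `eps ~ N(0,1)`; a 40 ms
#' raised-cosine pulse is placed at each beat and Gaussian sensor noise is
#' added. Ground-truth beat times are stored as an attribute.
#'
#' @param true_fh_bpm ground-truth mean heart rate, beats per minute
#' @param duration_s recording length, seconds (>= 60)
#' @param fs_hz sampling rate, Hz (default 1000, >= 100)
#' @param beat_cv coefficient of variation of inter-beat intervals (>= 0)
#' @param noise_sd sd of additive Gaussian noise (pulse amplitude is 1)
#' @param condition blockade condition label (routine/atropine/double)
#' @param test_temp_C,group,animal_id metadata
#' @param seed integer RNG seed
#' @return a `cardio_recording` object: list with `voltage`, `fs_hz`,
#'   `time_s`, ground-truth `beat_times_s`, and metadata
#' @export
gen_heart_signal <- function(true_fh_bpm, duration_s = 360, fs_hz = 1000,
                             beat_cv = 0.05, noise_sd = 0.05,
                             condition = "routine", test_temp_C = NA_real_,
                             group = NA_character_,
                             animal_id = NA_character_, seed = 1L) {
  stopifnot(true_fh_bpm > 0)
  if (fs_hz < 100) stop("fs_hz must be >= 100")
  if (duration_s < 60) stop("duration_s must be >= 60")
  if (beat_cv < 0) stop("beat_cv must be non-negative")
  rng <- local_rng(seed)

  mean_ibi <- 60 / true_fh_bpm
  n_max <- ceiling(duration_s / mean_ibi * (1 + 6 * beat_cv)) + 2
  ibis <- mean_ibi * (1 + beat_cv * stats::rnorm(n_max))
  ibis <- pmax(ibis, 0.1 * mean_ibi)  # guard against non-physical intervals
  beats <- cumsum(ibis)
  beats <- beats[beats < duration_s]

  n <- round(duration_s * fs_hz)
  v <- numeric(n)
  pulse_len <- max(3L, round(0.040 * fs_hz))
  pulse <- 0.5 * (1 - cos(2 * pi * seq_len(pulse_len) / (pulse_len + 1)))
  for (b in beats) {
    i0 <- floor(b * fs_hz) + 1L
    idx <- i0:min(i0 + pulse_len - 1L, n)
    v[idx] <- v[idx] + pulse[seq_along(idx)]
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)

  structure(list(voltage = v, fs_hz = fs_hz,
                 time_s = (seq_len(n) - 1) / fs_hz,
                 beat_times_s = beats, condition = condition,
                 test_temp_C = test_temp_C, group = group,
                 animal_id = animal_id, true_fh_bpm = true_fh_bpm),
            class = "cardio_recording")
}

#' Generate a synthetic CTmax heating ramp
#'
#' Temperature rises linearly from `start_C` at `rate_C_per_min`; Gaussian
#' sensor noise is added. The endpoint event (loss of escape response) is
#' annotated at the first sample whose noiseless temperature reaches
#' `ctmax_true_C`.
#'
#' @param start_C starting (acclimation) temperature, degC
#' @param rate_C_per_min heating rate, degC per minute (> 0)
#' @param ctmax_true_C ground-truth endpoint temperature (> start_C)
#' @param fs_hz sampling rate of the temperature channel, Hz (default 1)
#' @param noise_sd sd of sensor noise, degC
#' @param group,animal_id metadata
#' @param seed integer RNG seed
#' @return a `thermal_ramp` object: data.frame (`time_min`, `temp_C`,
#'   `event`) with `event_time_min` attribute
#' @export
gen_ctmax_ramp <- function(start_C, rate_C_per_min, ctmax_true_C,
                           fs_hz = 1, noise_sd = 0, group = NA_character_,
                           animal_id = NA_character_, seed = 1L) {
  if (rate_C_per_min <= 0) stop("rate_C_per_min must be positive")
  if (ctmax_true_C <= start_C) stop("ctmax_true_C must exceed start_C")
  rng <- local_rng(seed)
  event_min <- (ctmax_true_C - start_C) / rate_C_per_min
  t_min <- seq(0, event_min + 1, by = 1 / (fs_hz * 60))
  true_T <- start_C + rate_C_per_min * t_min
  temp <- true_T
  if (noise_sd > 0) temp <- temp + stats::rnorm(length(temp), 0, noise_sd)
  event_idx <- which(true_T >= ctmax_true_C)[1]
  out <- data.frame(time_min = t_min, temp_C = temp,
                    event = seq_along(t_min) == event_idx)
  structure(out, event_time_min = t_min[event_idx], group = group,
            animal_id = animal_id, ctmax_true_C = ctmax_true_C,
            class = c("thermal_ramp", "data.frame"))
}

#' Generate a synthetic hourly microhabitat temperature series
#'
#' Hourly logger samples built from a seasonal sinusoid (period 365 days,
#' warmest mid-January for a southern-hemisphere stream), a diel sinusoid
#' (warmest at 15:00, coolest at 03:00 -- both on-sample hours, so daily
#' extremes are exact at zero noise), and Gaussian noise.
#'
#' Defaults reproduce the wet-season (October--May) daily summaries of the
#' stream the study cohorts came from: the annual mean 21.3 degC plus the
#' ~0.6 degC seasonal offset of that window gives a wet-season mean near
#' 21.9 degC with mean daily extremes near 18.8 and 24.6 degC.
#'
#' @param start_date,end_date `Date` or parseable strings; end after start
#' @param daily_mean_C annual mean water temperature, degC
#' @param daily_amplitude_C half the diel range, degC
#' @param seasonal_amplitude_C half the seasonal range of daily means, degC
#' @param noise_sd sd of sensor noise, degC
#' @param seed integer RNG seed
#' @return a `habitat_series` object: data.frame (`timestamp` POSIXct UTC,
#'   `temp_C`)
#' @export
gen_habitat_series <- function(start_date, end_date, daily_mean_C = 21.3,
                               daily_amplitude_C = 2.9,
                               seasonal_amplitude_C = 1.5, noise_sd = 0,
                               seed = 1L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("end_date must be after start_date")
  rng <- local_rng(seed)
  ts <- seq(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end_date, "23:00:00"), tz = "UTC"),
            by = "hour")
  doy <- as.numeric(format(ts, "%j"))
  hr <- as.numeric(format(ts, "%H"))
  seasonal <- seasonal_amplitude_C * cos(2 * pi * (doy - 15) / 365)
  diel <- daily_amplitude_C * cos(2 * pi * (hr - 15) / 24)
  temp <- daily_mean_C + seasonal + diel
  if (noise_sd > 0) temp <- temp + stats::rnorm(length(temp), 0, noise_sd)
  structure(data.frame(timestamp = ts, temp_C = temp),
            class = c("habitat_series", "data.frame"))
}
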