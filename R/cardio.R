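#' Zero-phase low-pass filter a cardio recording
#'
#' Applies a 4th-order Butterworth low-pass (default 50 Hz, matching the
#' offline filtering used on 1 kHz electrode recordings) forwards and
#' backwards for zero phase shift.
#'
#' @param rec a `cardio_recording` (see [gen_heart_signal()]) or numeric
#'   vector (then `fs_hz` is required)
#' @param lowpass_hz cut-off frequency, Hz; must be below Nyquist
#' @param fs_hz sampling rate when `rec` is a bare vector
#' @return object of the same shape with filtered voltage
#' @export
filter_signal <- function(rec, lowpass_hz = 50, fs_hz = NULL) {
  if (inherits(rec, "cardio_recording")) {
    fs <- rec$fs_hz
    v <- rec$voltage
  } else {
    if (is.null(fs_hz)) stop("fs_hz required for a bare numeric signal")
    fs <- fs_hz
    v <- as.numeric(rec)
  }
  if (lowpass_hz >= fs / 2) {
    stop("lowpass_hz must be below the Nyquist frequency fs/2")
  }
  bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
  filtered <- signal::filtfilt(bf, v)
  if (inherits(rec, "cardio_recording")) {
    rec$voltage <- filtered
    rec
  } else {
    filtered
  }
}

#' Detect heartbeats in a filtered electrode signal
#'
#' Peak detection by amplitude threshold with a refractory period: samples
#' must exceed `k * MAD` of the signal (the electrode's amplitude scale is
#' arbitrary, so the threshold is self-calibrating), be local maxima, and be
#' separated by at least `min_interval_s` (default 0.2 s, a ~300 bpm
#' ceiling, comfortably above tadpole rates).
#'
#' @param rec a filtered `cardio_recording` or numeric vector
#' @param fs_hz sampling rate (taken from the recording when available)
#' @param min_interval_s refractory interval between accepted beats, s
#' @param threshold_k MAD multiplier for the auto-threshold (default 5)
#' @param threshold absolute threshold overriding the MAD rule, optional
#' @return a `beat_series`: list with `beat_times_s`, `fh_bpm` (mean rate
#'   over the whole detection span), `n_beats`, `fs_hz`
#' @export
detect_beats <- function(rec, fs_hz = NULL, min_interval_s = 0.2,
                         threshold_k = 5, threshold = NULL) {
  if (inherits(rec, "cardio_recording")) {
    fs <- rec$fs_hz
    v <- rec$voltage
  } else {
    if (is.null(fs_hz)) stop("fs_hz required for a bare numeric signal")
    fs <- fs_hz
    v <- as.numeric(rec)
  }
  if (length(v) < 60 * fs) stop("need at least 60 s of signal")
  if (is.null(threshold)) {
    s <- stats::mad(v)
    med <- stats::median(v)
    if (s > 0) {
      threshold <- med + threshold_k * s
    } else if (max(v) > med) {
      # noiseless sparse spikes: MAD collapses to 0; take half the peak
      threshold <- med + 0.5 * (max(v) - med)
    } else {
      stop("flat signal: cannot auto-threshold")
    }
  }
  n <- length(v)
  cand <- which(v > threshold)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] >= v[cand + 1]]
  if (length(cand) == 0) stop("no beats detected above threshold")
  # greedy refractory pass, strongest-first within each blackout
  refract <- round(min_interval_s * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refract) {
      keep <- c(keep, i)
      last <- i
    } else if (v[i] > v[keep[length(keep)]]) {
      keep[length(keep)] <- i  # replace with the taller peak in the window
      last <- i
    }
  }
  times <- (keep - 1) / fs
  if (length(times) < 2) stop("fewer than two beats detected")
  fh <- 60 * (length(times) - 1) / (times[length(times)] - times[1])
  structure(list(beat_times_s = times, fh_bpm = fh,
                 n_beats = length(times), fs_hz = fs),
            class = "beat_series")
}

#' Mean heart rate over the most stable 5-minute window
#'
#' Scans contiguous windows of `window_s` seconds (1 s stride) and selects
#' the one whose inter-beat intervals have minimum coefficient of variation
#' -- a reproducible stand-in for choosing a "visibly stable" stretch by
#' eye. Windows with CV above `stability_cv_max` are flagged unstable.
#'
#' @param beats a `beat_series` from [detect_beats()]
#' @param window_s analysis window length, seconds (default 300 = 5 min)
#' @param stability_cv_max maximum acceptable interval CV (default 0.25)
#' @return list with `fh_bpm`, `window` (start, end seconds), `cv`,
#'   `stable` flag
#' @export
mean_fh <- function(beats, window_s = 300, stability_cv_max = 0.25) {
  times <- beats$beat_times_s
  span <- times[length(times)] - times[1]
  if (span < window_s) {
    stop(sprintf("recording spans %.0f s of beats; need >= %.0f s",
                 span, window_s))
  }
  starts <- seq(times[1], times[length(times)] - window_s, by = 1)
  best <- NULL
  for (s in starts) {
    w <- times[times >= s & times <= s + window_s]
    if (length(w) < 3) next
    ibi <- diff(w)
    cv <- stats::sd(ibi) / mean(ibi)
    if (is.null(best) || cv < best$cv) {
      best <- list(cv = cv, start = s,
                   fh = 60 * (length(w) - 1) / (w[length(w)] - w[1]))
    }
  }
  if (is.null(best)) stop("no qualifying window found")
  list(fh_bpm = best$fh,
       window = c(start_s = best$start, end_s = best$start + window_s),
       cv = best$cv,
       stable = best$cv <= stability_cv_max)
}

#' Partition autonomic tones from a blockade experiment
#'
#' Given heart rates in the routine state, after muscarinic (atropine)
#' blockade and after double (atropine + sotalol) blockade, expresses the
#' cholinergic (vagal) and adrenergic (sympathetic) tones as percentages of
#' the intrinsic rate, which is the double-blockade rate:
#' `cholinergic = 100 * (fh_atropine - fh_routine) / fh_double`,
#' `adrenergic = 100 * (fh_atropine - fh_double) / fh_double`.
#' Negative tones (e.g. atropine lowering rate) are kept and flagged.
#'
#' @param fh_routine,fh_atropine,fh_double heart rates, beats per minute
#' @return a `tone_profile`: list with the three input rates,
#'   `cholinergic_pct`, `adrenergic_pct`, `intrinsic_fh_bpm` and a
#'   `negative_tone` flag
#' @export
autonomic_tones <- function(fh_routine, fh_atropine, fh_double) {
  stopifnot(is.finite(fh_routine), is.finite(fh_atropine),
            is.finite(fh_double))
  if (fh_double <= 0) stop("double-blockade (intrinsic) rate must be positive")
  if (fh_routine <= 0 || fh_atropine <= 0) stop("heart rates must be positive")
  chol <- 100 * (fh_atropine - fh_routine) / fh_double
  adre <- 100 * (fh_atropine - fh_double) / fh_double
  structure(list(fh_routine = fh_routine, fh_atropine = fh_atropine,
                 fh_double = fh_double,
                 cholinergic_pct = chol, adrenergic_pct = adre,
                 intrinsic_fh_bpm = fh_double,
                 negative_tone = chol < 0 || adre < 0),
            class = "tone_profile")
}

#' Heart rate from a raw recording (filter + detect + stable window)
#'
#' Convenience chain: [filter_signal()], [detect_beats()], [mean_fh()].
#'
#' @param rec a `cardio_recording`
#' @param lowpass_hz low-pass cut-off, Hz
#' @param window_s stable-window length, seconds
#' @param min_interval_s beat refractory interval, seconds
#' @return [mean_fh()] output
#' @export
fh_from_recording <- function(rec, lowpass_hz = 50, window_s = 300,
                              min_interval_s = 0.2) {
  filtered <- filter_signal(rec, lowpass_hz)
  beats <- detect_beats(filtered, min_interval_s = min_interval_s)
  mean_fh(beats, window_s = window_s)
}
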