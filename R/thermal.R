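#' Extract the critical thermal maximum from a heating ramp
#'
#' CTmax is read as the (optionally median-smoothed) temperature at the
#' annotated behavioural endpoint event. The endpoint is an observational
#' input (loss of escape response scored during the trial), never inferred
#' from the temperature trace itself.
#'
#' @param ramp a `thermal_ramp` (see [gen_ctmax_ramp()]) or data.frame with
#'   `time_min`, `temp_C` and a logical `event` column (or an
#'   `event_time_min` attribute)
#' @param smoothing_s width of a running-median smoother applied to the
#'   temperature channel before lookup, seconds; 0 disables (default 5)
#' @return a `ctmax_result`: list with `ctmax_C`, `heating_rate_C_min`,
#'   `event_time_min`, `group`, `animal_id`
#' @export
extract_ctmax <- function(ramp, smoothing_s = 5) {
  ev_time <- attr(ramp, "event_time_min")
  if (is.null(ev_time)) {
    if (!"event" %in% names(ramp) || !any(ramp$event)) {
      stop("ramp has no annotated endpoint event; not a CTmax trial")
    }
    ev_time <- ramp$time_min[which(ramp$event)[1]]
  }
  if (ev_time < min(ramp$time_min) || ev_time > max(ramp$time_min)) {
    stop("endpoint event lies outside the recorded ramp")
  }
  temp <- ramp$temp_C
  if (smoothing_s > 0 && nrow(ramp) > 3) {
    dt_s <- stats::median(diff(ramp$time_min)) * 60
    k <- max(3L, 2L * floor(smoothing_s / dt_s / 2) + 1L)  # odd window
    if (k < nrow(ramp)) temp <- stats::runmed(temp, k)
  }
  idx <- which.min(abs(ramp$time_min - ev_time))
  pre <- ramp$time_min <= ev_time
  rate <- estimate_heating_rate(ramp[pre, , drop = FALSE])
  structure(list(ctmax_C = temp[idx],
                 heating_rate_C_min = rate,
                 event_time_min = ev_time,
                 group = attr(ramp, "group") %||% NA_character_,
                 animal_id = attr(ramp, "animal_id") %||% NA_character_),
            class = "ctmax_result")
}

#' Estimate the realized heating rate of a ramp
#'
#' Ordinary least-squares slope of temperature on time over the supplied
#' span (typically start to endpoint). A non-positive slope is reported with
#' a warning: that trace is not a heating ramp.
#'
#' @param ramp data.frame with `time_min` and `temp_C`
#' @return heating rate, degC per minute
#' @export
estimate_heating_rate <- function(ramp) {
  if (nrow(ramp) < 10) stop("need at least 10 samples to estimate a rate")
  if (length(unique(ramp$time_min)) < 2) stop("degenerate time axis")
  fit <- stats::lm.fit(cbind(1, ramp$time_min), ramp$temp_C)
  rate <- unname(fit$coefficients[2])
  if (rate < 1e-10) warning("non-positive slope: trace is not a heating ramp")
  rate
}

#' Warming tolerance
#'
#' The thermal safety margin `WT = CTmax - Tmax`: how far the habitat's
#' maximum temperature sits below the animal's critical limit. A negative
#' value (habitat already exceeds tolerance) is returned with a warning.
#'
#' @param ctmax_C critical thermal maximum, degC
#' @param habitat_tmax_C maximum habitat temperature, degC -- conventionally
#'   the season-filtered mean daily maximum (see [period_summary()])
#' @return warming tolerance, degC
#' @export
warming_tolerance <- function(ctmax_C, habitat_tmax_C) {
  stopifnot(is.finite(ctmax_C), is.finite(habitat_tmax_C))
  wt <- ctmax_C - habitat_tmax_C
  if (wt < 0) warning("negative warming tolerance: habitat maximum exceeds CTmax")
  wt
}
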