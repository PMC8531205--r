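#' Split a respirometry trace into sealed-phase segments
#'
#' Extracts the contiguous sealed (closed-chamber) segments of an
#' intermittent-flow trace and trims a leading dead time from each, to
#' discard mixing transients after the chamber closes.
#'
#' @param trace an `o2_trace` (see [gen_o2_trace()]) or a data.frame with
#'   `time_h`, `sat_pct`, `temp_C`, `phase` columns
#' @param dead_time_s leading seconds dropped from each sealed segment
#'   (default 60)
#' @return list of data.frames, one per sealed cycle, each carrying a
#'   `cycle_index` attribute
#' @export
segment_cycles <- function(trace, dead_time_s = 60) {
  stopifnot(all(c("time_h", "sat_pct", "phase") %in% names(trace)))
  sealed <- trace$phase == "seal"
  if (!any(sealed)) stop("trace contains no sealed-phase samples")
  # contiguous runs of sealed samples
  r <- rle(sealed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seal_runs <- which(r$values)
  segs <- vector("list", length(seal_runs))
  for (k in seq_along(seal_runs)) {
    i <- seal_runs[k]
    seg <- trace[starts[i]:ends[i], , drop = FALSE]
    t0 <- seg$time_h[1]
    seg <- seg[(seg$time_h - t0) * 3600 >= dead_time_s, , drop = FALSE]
    attr(seg, "cycle_index") <- k
    segs[[k]] <- seg
  }
  segs
}

#' Fit the oxygen-decline slope of one sealed segment
#'
#' Converts percent air saturation to concentration (umol O2 per litre)
#' through the solubility model at the segment's recorded temperature, then
#' fits ordinary least squares of concentration on time (hours). The slope
#' is the oxygen content change dC/dt in umol per litre per hour (negative
#' when the animal consumes oxygen).
#'
#' @param segment one element of [segment_cycles()] output
#' @param pressure_kPa barometric pressure, kPa
#' @return a `slope_estimate`: list with `cycle_index`, `slope_umol_L_h`,
#'   `r2`, `sat_min_pct`, `sat_max_pct`, `n_points`
#' @export
fit_slope <- function(segment, pressure_kPa = 101.325) {
  if (nrow(segment) < 10) stop("need at least 10 points to fit a slope")
  if (length(unique(segment$time_h)) < 2) stop("degenerate time axis")
  conc <- sat_to_conc(segment$sat_pct, segment$temp_C, pressure_kPa)
  fit <- stats::lm.fit(cbind(1, segment$time_h), conc)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((conc - mean(conc))^2)
  # a flat response carries no rate information: define r2 = 0 so QC rejects
  r2 <- if (ss_tot <= 0) 0 else max(0, 1 - ss_res / ss_tot)
  structure(list(
    cycle_index = attr(segment, "cycle_index") %||% NA_integer_,
    slope_umol_L_h = slope,
    r2 = r2,
    sat_min_pct = min(segment$sat_pct),
    sat_max_pct = max(segment$sat_pct),
    n_points = nrow(segment)
  ), class = "slope_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quality-filter slope estimates
#'
#' A slope passes if its coefficient of determination meets the threshold
#' (`r2 >= r2_min`, boundary inclusive) and its minimum saturation stayed at
#' or above the floor (`sat_min >= sat_floor_pct`). Rejections carry
#' machine-readable reason codes (`low_r2`, `sat_floor`).
#'
#' @param estimates list of `slope_estimate` objects
#' @param r2_min minimum r-squared (default 0.95)
#' @param sat_floor_pct minimum allowed saturation, percent (default 80)
#' @return list with elements `passed` (list of estimates) and `rejected`
#'   (list of estimates, each with a `reasons` character vector attached)
#' @export
qc_filter <- function(estimates, r2_min = 0.95, sat_floor_pct = 80) {
  if (inherits(estimates, "slope_estimate")) estimates <- list(estimates)
  passed <- list(); rejected <- list()
  for (e in estimates) {
    reasons <- character(0)
    if (e$r2 < r2_min) reasons <- c(reasons, "low_r2")
    if (e$sat_min_pct < sat_floor_pct) reasons <- c(reasons, "sat_floor")
    if (length(reasons) == 0) {
      passed[[length(passed) + 1]] <- e
    } else {
      e$reasons <- reasons
      rejected[[length(rejected) + 1]] <- e
    }
  }
  list(passed = passed, rejected = rejected)
}

#' Compute a metabolic-rate estimate from a fitted slope
#'
#' Applies the intermittent-flow equation: total oxygen consumption is the
#' magnitude of the concentration slope times the effective water volume
#' `V_RE = (chamber_ml - mass_g) / 1000` litres (organism volume from its
#' mass at density 1 kg per litre), minus the background (control) rate;
#' the mass-specific rate divides by organism mass. A negative
#' post-background total is kept and flagged (`qc_passed = FALSE`) rather
#' than clipped, since it signals a calibration problem.
#'
#' @param slope a `slope_estimate`
#' @param chamber_ml total respirometer volume, mL
#' @param mass_g organism wet mass, g
#' @param background_umol_h background oxygen consumption measured from
#'   empty-chamber controls, umol per h (default 0)
#' @param test_temp_C,trial_kind,group,animal_id metadata carried through
#' @return a `metabolic_estimate`: list with `mo2_total_umol_h`,
#'   `mo2_mass_specific_umol_g_h`, `v_re_L`, `background_umol_h`, QC flag
#'   and metadata
#' @export
compute_mo2 <- function(slope, chamber_ml, mass_g, background_umol_h = 0,
                        test_temp_C = NA_real_, trial_kind = NA_character_,
                        group = NA_character_, animal_id = NA_character_) {
  if (mass_g <= 0) stop("mass_g must be positive")
  if (chamber_ml <= mass_g) {
    stop("chamber volume must exceed the organism's displacement volume")
  }
  v_re_L <- (chamber_ml - mass_g) / 1000
  total <- abs(slope$slope_umol_L_h) * v_re_L - background_umol_h
  structure(list(
    mo2_total_umol_h = total,
    mo2_mass_specific_umol_g_h = total / mass_g,
    v_re_L = v_re_L,
    background_umol_h = background_umol_h,
    slope_umol_L_h = slope$slope_umol_L_h,
    r2 = slope$r2,
    cycle_index = slope$cycle_index,
    test_temp_C = test_temp_C,
    trial_kind = trial_kind,
    group = group,
    animal_id = animal_id,
    qc_passed = total >= 0
  ), class = "metabolic_estimate")
}

#' Average duplicate metabolic determinations
#'
#' Each animal-by-temperature condition is measured in duplicate cycles;
#' this averages the QC-passed duplicates into a single estimate, recording
#' how many cycles contributed. With zero passed estimates a missing-value
#' record is returned (never silently dropped), carrying the rejection
#' reasons.
#'
#' @param estimates list of `metabolic_estimate` objects for one animal at
#'   one test temperature (QC-passed), possibly empty
#' @param reasons character vector of rejection reasons when all cycles
#'   failed QC
#' @return list with `mo2_total_umol_h`, `mo2_mass_specific_umol_g_h`
#'   (NA when nothing passed), `n_used`, `reasons`
#' @export
summarize_duplicates <- function(estimates, reasons = character(0)) {
  estimates <- Filter(function(e) isTRUE(e$qc_passed), estimates)
  if (length(estimates) == 0) {
    return(list(mo2_total_umol_h = NA_real_,
                mo2_mass_specific_umol_g_h = NA_real_,
                n_used = 0L, reasons = reasons))
  }
  list(
    mo2_total_umol_h = mean(vapply(estimates, `[[`, 1, "mo2_total_umol_h")),
    mo2_mass_specific_umol_g_h =
      mean(vapply(estimates, `[[`, 1, "mo2_mass_specific_umol_g_h")),
    n_used = length(estimates),
    reasons = character(0)
  )
}

#' Measure background respiration from an empty-chamber control trace
#'
#' Runs the control trace through the same segmentation and slope machinery
#' as animal trials and converts the mean sealed-phase decline into an
#' absolute rate over the chamber water volume. The r-squared criterion is
#' not applied: a control trace with a near-zero rate legitimately has low
#' explanatory power, and rejecting it would silently zero the correction.
#' The saturation floor still applies.
#'
#' @param trace an `o2_trace` recorded without an animal (any `mass_g`
#'   metadata on it is treated as displacement of instrument fittings)
#' @param dead_time_s leading dead time per sealed phase, seconds
#' @param sat_floor_pct QC saturation floor, percent
#' @param pressure_kPa barometric pressure, kPa
#' @return background oxygen consumption, umol per hour
#' @export
measure_background <- function(trace, dead_time_s = 60, sat_floor_pct = 80,
                               pressure_kPa = 101.325) {
  segs <- segment_cycles(trace, dead_time_s)
  slopes <- lapply(segs, fit_slope, pressure_kPa = pressure_kPa)
  qc <- qc_filter(slopes, r2_min = 0, sat_floor_pct = sat_floor_pct)
  if (length(qc$passed) == 0) stop("no usable control cycles")
  v_L <- (attr(trace, "chamber_ml") - (attr(trace, "mass_g") %||% 0)) / 1000
  mean(vapply(qc$passed, function(s) abs(s$slope_umol_L_h), 1)) * v_L
}

#' Run the full respirometry pipeline on one trace
#'
#' Convenience chain: [segment_cycles()] then [fit_slope()] per cycle,
#' [qc_filter()], [compute_mo2()] per passed cycle and
#' [summarize_duplicates()]. Metadata (chamber volume, mass, trial kind) is
#' read from the trace attributes unless overridden.
#'
#' @param trace an `o2_trace`
#' @param background_umol_h background rate to subtract, umol/h
#' @param r2_min,sat_floor_pct QC thresholds (see [qc_filter()])
#' @param dead_time_s leading dead time per sealed phase, seconds
#' @param pressure_kPa barometric pressure, kPa
#' @return [summarize_duplicates()] output plus `n_cycles`, `n_rejected`
#' @export
mo2_from_trace <- function(trace, background_umol_h = 0, r2_min = 0.95,
                           sat_floor_pct = 80, dead_time_s = 60,
                           pressure_kPa = 101.325) {
  segs <- segment_cycles(trace, dead_time_s)
  slopes <- lapply(segs, fit_slope, pressure_kPa = pressure_kPa)
  qc <- qc_filter(slopes, r2_min, sat_floor_pct)
  ests <- lapply(qc$passed, compute_mo2,
                 chamber_ml = attr(trace, "chamber_ml"),
                 mass_g = attr(trace, "mass_g"),
                 background_umol_h = background_umol_h,
                 test_temp_C = trace$temp_C[1],
                 trial_kind = attr(trace, "trial_kind"),
                 group = attr(trace, "group"),
                 animal_id = attr(trace, "animal_id"))
  reasons <- unlist(lapply(qc$rejected, `[[`, "reasons"))
  out <- summarize_duplicates(ests, reasons = unique(reasons))
  out$n_cycles <- length(segs)
  out$n_rejected <- length(qc$rejected)
  out
}
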