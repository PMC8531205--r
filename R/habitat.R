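#' Daily temperature summaries from an hourly logger series
#'
#' Groups hourly samples by calendar date and reports the daily minimum,
#' maximum and mean. Days with fewer than `min_coverage` samples are flagged
#' (gaps happen when a logger is serviced or emerges from the water) but
#' still summarized.
#'
#' @param series a `habitat_series` (see [gen_habitat_series()]) or
#'   data.frame with `timestamp` (POSIXct) and `temp_C`
#' @param min_coverage minimum samples per day for full coverage
#'   (default 20 of 24)
#' @return data.frame: `date`, `tmin_C`, `tmax_C`, `tmean_C`, `n_samples`,
#'   `low_coverage`
#' @export
daily_stats <- function(series, min_coverage = 20) {
  stopifnot(all(c("timestamp", "temp_C") %in% names(series)))
  ok <- is.finite(series$temp_C)
  series <- series[ok, , drop = FALSE]
  if (nrow(series) == 0) stop("empty logger series")
  date <- as.Date(series$timestamp, tz = "UTC")
  sp <- split(series$temp_C, date)
  out <- data.frame(
    date = as.Date(names(sp)),
    tmin_C = vapply(sp, min, 1),
    tmax_C = vapply(sp, max, 1),
    tmean_C = vapply(sp, mean, 1),
    n_samples = vapply(sp, length, 1L),
    row.names = NULL
  )
  out$low_coverage <- out$n_samples < min_coverage
  out[order(out$date), , drop = FALSE]
}

#' Season-filtered means of the daily temperature statistics
#'
#' Filters daily summaries to a month window -- wrap-aware, so October
#' through May spans the year end -- and reports the mean and sd (and
#' s.e.m.) of the daily minima, maxima and means. The window mirrors a
#' wet-season filter: only months with water in the stream.
#'
#' @param dailies output of [daily_stats()]
#' @param start_month,end_month first and last calendar months included
#'   (1--12); `start_month > end_month` wraps the year end (default 10 and
#'   5: October--May)
#' @return data.frame with one row per statistic (`tmin`, `tmax`, `tmean`):
#'   `mean`, `sd`, `sem`, `n_days`
#' @export
period_summary <- function(dailies, start_month = 10, end_month = 5) {
  stopifnot(start_month %in% 1:12, end_month %in% 1:12)
  m <- as.integer(format(dailies$date, "%m"))
  keep <- if (start_month <= end_month) {
    m >= start_month & m <= end_month
  } else {
    m >= start_month | m <= end_month
  }
  d <- dailies[keep, , drop = FALSE]
  if (nrow(d) == 0) stop("no days fall inside the month window")
  one <- function(x, name) {
    data.frame(statistic = name, mean = mean(x), sd = stats::sd(x),
               sem = stats::sd(x) / sqrt(length(x)), n_days = length(x),
               stringsAsFactors = FALSE)
  }
  rbind(one(d$tmin_C, "tmin"), one(d$tmax_C, "tmax"), one(d$tmean_C, "tmean"))
}

#' Temperature frequency histogram on half-degree-centered bins
#'
#' Bins of width `bin_width_C` centered on multiples of the width (for the
#' default 0.5 degC: centers ..., 20.0, 20.5, 21.0, ... with edges at
#' 0.25-offsets), left-closed and right-open. Counts always sum to the
#' number of non-missing samples.
#'
#' @param series a `habitat_series` or data.frame with `temp_C`, or a bare
#'   numeric vector of temperatures
#' @param bin_width_C bin width, degC (default 0.5)
#' @return data.frame: `bin_center_C`, `count`
#' @export
temp_histogram <- function(series, bin_width_C = 0.5) {
  stopifnot(bin_width_C > 0)
  x <- if (is.numeric(series)) series else series$temp_C
  x <- x[is.finite(x)]
  centers <- floor(x / bin_width_C + 0.5) * bin_width_C
  tab <- table(centers)
  data.frame(bin_center_C = as.numeric(names(tab)),
             count = as.integer(tab),
             row.names = NULL)
}
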