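#' CSV schemas for raw input files
#'
#' Column names and types for each raw file kind the pipeline reads:
#' `trace` (respirometry), `ramp` (CTmax trial), `signal` (heart
#' electrode), `logger` (habitat temperature), `cohort` (biometrics).
#'
#' @return named list: for each schema id, a named character vector of
#'   column types
#' @export
io_schemas <- function() {
  list(
    trace = c(time_s = "numeric", sat_pct = "numeric", temp_C = "numeric",
              phase = "character"),
    ramp = c(time_s = "numeric", temp_C = "numeric", event = "logical"),
    signal = c(time_s = "numeric", voltage = "numeric"),
    logger = c(timestamp = "POSIXct", temp_C = "numeric"),
    cohort = c(animal_id = "character", group = "character",
               mass_g = "numeric", tl_mm = "numeric", pl_mm = "numeric",
               bw_mm = "numeric")
  )
}

#' Read a raw CSV against a declared schema
#'
#' Reads a UTF-8 CSV, checks that every mandatory column is present (an
#' error names the first missing one), coerces columns to their schema
#' types, and collects malformed rows (values that fail coercion) into a
#' reject report attached as the `"rejects"` attribute -- malformed data is
#' reported, never silently dropped.
#'
#' @param path file path
#' @param schema one of `names(io_schemas())`
#' @return data.frame of valid typed rows, with a `rejects` attribute
#'   (data.frame: `row`, `reason`) when any row failed
#' @export
read_trace_csv <- function(path, schema = "trace") {
  schemas <- io_schemas()
  if (!schema %in% names(schemas)) {
    stop("unknown schema: ", schema)
  }
  spec <- schemas[[schema]]
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot read ", path, ": ", conditionMessage(e)))
  if (nrow(raw) == 0) stop("empty file: ", path)
  missing_cols <- setdiff(names(spec), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column: ", missing_cols[1])
  }
  rejects <- data.frame(row = integer(0), reason = character(0))
  bad <- rep(FALSE, nrow(raw))
  for (col in names(spec)) {
    v <- raw[[col]]
    coerced <- switch(spec[[col]],
      numeric = suppressWarnings(as.numeric(v)),
      character = as.character(v),
      logical = suppressWarnings(as.logical(v)),
      POSIXct = parse_timestamp(as.character(v)))
    newly_bad <- is.na(coerced) & !is.na(v) & !bad
    if (any(newly_bad)) {
      rejects <- rbind(rejects, data.frame(
        row = which(newly_bad),
        reason = paste0("unparseable ", col)))
      bad <- bad | newly_bad
    }
    raw[[col]] <- coerced
  }
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(rejects) > 0) attr(out, "rejects") <- rejects
  out
}

# multi-format ISO-ish timestamp parser that yields NA (for the reject
# report) instead of erroring on malformed values
parse_timestamp <- function(v) {
  out <- as.POSIXct(rep(NA_real_, length(v)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%d %H:%M")) {
    idx <- is.na(out)
    if (!any(idx)) break
    out[idx] <- as.POSIXct(strptime(v[idx], fmt, tz = "UTC"))
  }
  out
}

#' Construct pipeline objects from schema data.frames
#'
#' Converters from the raw CSV schemas (see [read_trace_csv()]) to the
#' typed objects the analysis functions consume.
#'
#' @param df a data.frame read with the matching schema
#' @param chamber_ml,mass_g,trial_kind,group,animal_id trace metadata
#' @return the corresponding pipeline object
#' @export
as_o2_trace <- function(df, chamber_ml, mass_g, trial_kind = "routine",
                        group = NA_character_, animal_id = NA_character_) {
  stopifnot(all(c("time_s", "sat_pct", "temp_C", "phase") %in% names(df)))
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("time must be strictly increasing")
  }
  if (any(df$sat_pct < 0 | df$sat_pct > 105)) {
    stop("saturation outside [0, 105]%")
  }
  if (chamber_ml <= 0 || mass_g <= 0) stop("chamber_ml and mass_g must be positive")
  out <- data.frame(time_h = df$time_s / 3600, sat_pct = df$sat_pct,
                    temp_C = df$temp_C, phase = df$phase)
  structure(out, chamber_ml = chamber_ml, mass_g = mass_g,
            trial_kind = trial_kind, group = group, animal_id = animal_id,
            class = c("o2_trace", "data.frame"))
}

#' @rdname as_o2_trace
#' @export
as_thermal_ramp <- function(df, group = NA_character_,
                            animal_id = NA_character_) {
  stopifnot(all(c("time_s", "temp_C", "event") %in% names(df)))
  out <- data.frame(time_min = df$time_s / 60, temp_C = df$temp_C,
                    event = as.logical(df$event))
  ev <- which(out$event)
  structure(out,
            event_time_min = if (length(ev)) out$time_min[ev[1]] else NULL,
            group = group, animal_id = animal_id,
            class = c("thermal_ramp", "data.frame"))
}

#' @rdname as_o2_trace
#' @param fs_hz sampling rate; inferred from the time column when omitted
#' @param condition,test_temp_C recording metadata
#' @export
as_cardio_recording <- function(df, fs_hz = NULL, condition = "routine",
                                test_temp_C = NA_real_,
                                group = NA_character_,
                                animal_id = NA_character_) {
  stopifnot(all(c("time_s", "voltage") %in% names(df)))
  if (is.null(fs_hz)) fs_hz <- 1 / stats::median(diff(df$time_s))
  structure(list(voltage = df$voltage, fs_hz = fs_hz, time_s = df$time_s,
                 beat_times_s = NULL, condition = condition,
                 test_temp_C = test_temp_C, group = group,
                 animal_id = animal_id),
            class = "cardio_recording")
}

#' @rdname as_o2_trace
#' @export
as_habitat_series <- function(df) {
  stopifnot(all(c("timestamp", "temp_C") %in% names(df)))
  if (is.unsorted(as.numeric(df$timestamp), strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  structure(data.frame(timestamp = df$timestamp, temp_C = df$temp_C),
            class = c("habitat_series", "data.frame"))
}

#' Write a raw object to its schema CSV
#'
#' Inverse of [read_trace_csv()] for the generated types; round-trips all
#' typed fields losslessly (timestamps as ISO-8601, 15 significant digits
#' for numerics).
#'
#' @param x an `o2_trace`, `thermal_ramp`, `cardio_recording`,
#'   `habitat_series`, or plain data.frame matching a schema
#' @param path output file path
#' @param schema schema id (inferred from the object class when omitted)
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(x, path, schema = NULL) {
  if (is.null(schema)) {
    schema <- if (inherits(x, "o2_trace")) "trace"
      else if (inherits(x, "thermal_ramp")) "ramp"
      else if (inherits(x, "cardio_recording")) "signal"
      else if (inherits(x, "habitat_series")) "logger"
      else stop("schema must be given for a plain data.frame")
  }
  df <- switch(schema,
    trace = data.frame(time_s = x$time_h * 3600, sat_pct = x$sat_pct,
                       temp_C = x$temp_C, phase = x$phase),
    ramp = data.frame(time_s = x$time_min * 60, temp_C = x$temp_C,
                      event = x$event),
    signal = data.frame(time_s = x$time_s, voltage = x$voltage),
    logger = data.frame(timestamp = format(x$timestamp,
                                           "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                        temp_C = x$temp_C),
    cohort = x,
    stop("unknown schema: ", schema))
  old <- options(digits = 15); on.exit(options(old))
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
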