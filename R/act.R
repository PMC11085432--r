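#' Daily accumulated cooling temperature of a regime
#'
#' The ACT index accrues, per day, the day-time and night-time temperature
#' differentials between the vegetative stage and the cooling room, each
#' weighted by its duration:
#'
#'   `ACT/day = (T_vd - T_cd) * H_d + (T_vn - T_cn) * H_n`  (deg C * h)
#'
#' When the cooling room is not actually cooler than the vegetative
#' reference there is no physiological cooling signal, so each term is
#' clamped at zero independently (negative differentials never subtract
#' from the accumulated total).
#'
#' @param regime A [temperature_regime()].
#' @param clamp If `TRUE` (default) negative day/night differentials are
#'   clamped to zero per term; `FALSE` returns the raw algebraic sum, which
#'   is only useful for sensitivity checks.
#' @param inhibition_threshold Optional temperature (deg C): when the
#'   cooling-room day temperature meets or exceeds it, the whole day's
#'   accumulation is zeroed.  High day temperatures are known to inhibit
#'   spike initiation in Phalaenopsis (reported thresholds are around
#'   28-29 deg C); the rule is off by default because the base index does
#'   not include it.
#' @return Degree-hours accumulated per day (a single number).
#'
#' @examples
#' daily_act(temperature_regime(27, 23))   # 5*14 + 4*10 = 110 degC*h/day
#' daily_act(temperature_regime(32, 24))   # 10*14 + 5*10 = 190 degC*h/day
#' @seealso [daily_day_act()] for the day-term-only variant,
#'   [accumulate_regime()] for multi-day series.
#' @export
daily_act <- function(regime, clamp = TRUE, inhibition_threshold = NULL) {
  stopifnot(is_temp_regime(regime))
  if (!is.null(inhibition_threshold) && regime$T_cd >= inhibition_threshold) {
    return(0)
  }
  dday <- regime$T_vd - regime$T_cd
  dnight <- regime$T_vn - regime$T_cn
  if (clamp) {
    dday <- max(0, dday)
    dnight <- max(0, dnight)
  }
  dday * regime$H_d + dnight * regime$H_n
}

#' Daily day-only accumulated cooling temperature
#'
#' The Day-ACT variant keeps only the day-time term,
#' `(T_vd - T_cd) * H_d`, and is used to test whether day-time cooling
#' alone explains spike induction across varieties.
#'
#' @inheritParams daily_act
#' @return Degree-hours accumulated per day from the day term only.
#' @examples
#' daily_day_act(temperature_regime(27, 23))  # 5*14 = 70 degC*h/day
#' @export
daily_day_act <- function(regime, clamp = TRUE, inhibition_threshold = NULL) {
  stopifnot(is_temp_regime(regime))
  if (!is.null(inhibition_threshold) && regime$T_cd >= inhibition_threshold) {
    return(0)
  }
  dday <- regime$T_vd - regime$T_cd
  if (clamp) dday <- max(0, dday)
  dday * regime$H_d
}

new_act_series <- function(day, increment, index) {
  df <- data.frame(day = as.integer(day),
                   increment_c_h = increment,
                   cumulative_c_h = cumsum(increment))
  structure(df, class = c("act_series", "data.frame"), index = index)
}

#' Accumulate cooling degree-hours over days in the cooling room
#'
#' Builds the per-day and cumulative ACT series for a constant set-point
#' regime.  Under a fixed regime the increment is the same every day, so
#' the cumulative value after `d` days is `d` times the daily increment.
#'
#' @inheritParams daily_act
#' @param days Number of days in the cooling room (positive integer).
#' @param index `"full"` for the day+night index (default) or
#'   `"day_only"` for the Day-ACT variant.
#' @return An `act_series` data frame with columns `day`, `increment_c_h`
#'   and `cumulative_c_h`.
#' @examples
#' s <- accumulate_regime(phal_regime("KHM1220"), days = 10)
#' s$cumulative_c_h[10]  # 1100
#' @export
accumulate_regime <- function(regime, days, index = c("full", "day_only"),
                              clamp = TRUE, inhibition_threshold = NULL) {
  stopifnot(is_temp_regime(regime))
  index <- match.arg(index)
  if (!is.numeric(days) || length(days) != 1L || !is.finite(days) ||
      days < 1 || days != floor(days)) {
    stop("'days' must be a positive integer", call. = FALSE)
  }
  inc <- if (index == "full") {
    daily_act(regime, clamp = clamp, inhibition_threshold = inhibition_threshold)
  } else {
    daily_day_act(regime, clamp = clamp, inhibition_threshold = inhibition_threshold)
  }
  new_act_series(seq_len(days), rep(inc, days), index)
}

#' @export
print.act_series <- function(x, ...) {
  cat(sprintf("ACT series (%s index), %d day(s), cumulative %g degC*h\n",
              attr(x, "index"), nrow(x), x$cumulative_c_h[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... %d more day(s)\n", nrow(x) - 10))
  invisible(x)
}

#' Construct an hourly (or sub-hourly) temperature log
#'
#' @param timestamp `POSIXct` vector, strictly increasing.
#' @param temp_c Recorded temperatures (deg C), same length.
#' @param interval_hours Declared sampling interval in hours; inferred from
#'   the median timestamp spacing when omitted.  A gap larger than twice
#'   the interval is an error (logged data with holes must be repaired
#'   before accumulation, not silently bridged).
#' @return A `temp_log` data frame.
#' @export
temperature_log <- function(timestamp, temp_c, interval_hours = NULL) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("'timestamp' must be POSIXct", call. = FALSE)
  }
  if (length(timestamp) != length(temp_c)) {
    stop("'timestamp' and 'temp_c' lengths differ", call. = FALSE)
  }
  if (length(timestamp) < 2L) stop("log needs at least 2 records", call. = FALSE)
  if (!all(is.finite(temp_c))) stop("temperatures must be finite", call. = FALSE)
  dt <- as.numeric(difftime(timestamp[-1], timestamp[-length(timestamp)],
                            units = "hours"))
  if (any(dt <= 0)) {
    stop(sprintf("timestamps must be strictly increasing (violation at record %d)",
                 which(dt <= 0)[1] + 1L), call. = FALSE)
  }
  if (is.null(interval_hours)) interval_hours <- stats::median(dt)
  gap <- which(dt > 2 * interval_hours + 1e-9)
  if (length(gap)) {
    stop(sprintf("gap in temperature log: no record between %s and %s (interval %g h, gap %g h)",
                 format(timestamp[gap[1]]), format(timestamp[gap[1] + 1L]),
                 interval_hours, dt[gap[1]]), call. = FALSE)
  }
  structure(data.frame(timestamp = timestamp, temp_c = temp_c),
            class = c("temp_log", "data.frame"),
            interval_hours = interval_hours)
}

#' Read an hourly temperature log from CSV
#'
#' Expects the header `timestamp,temp_c` with ISO-8601 timestamps.
#'
#' @param path CSV file path.
#' @param tz Time zone for parsing (default UTC).
#' @inheritParams temperature_log
#' @return A `temp_log`.
#' @export
read_temperature_log <- function(path, tz = "UTC", interval_hours = NULL) {
  if (!file.exists(path)) stop(sprintf("log file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(df))) {
    stop(sprintf("log file %s must have columns 'timestamp' and 'temp_c'", path),
         call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) {
    stop(sprintf("unparseable timestamp at row %d of %s", which(is.na(ts))[1], path),
         call. = FALSE)
  }
  temperature_log(ts, df$temp_c, interval_hours = interval_hours)
}

#' Accumulate cooling degree-hours from a recorded temperature log
#'
#' Generalizes the set-point index to measured conditions: every sample
#' contributes `max(0, T_ref - T_sample) * interval_hours`, where the
#' vegetative reference `T_ref` is the day or night reference according to
#' the sample's clock time relative to the lights-on window.  Days are
#' calendar days of the log's time zone; on a square-wave log that matches
#' a set-point regime the result equals [accumulate_regime()] exactly.
#'
#' @param log A [temperature_log()] (or path readable by
#'   [read_temperature_log()]).
#' @param T_vd,T_vn Vegetative day and night reference temperatures (deg C).
#' @param lights_on Clock hour at which the photoperiod starts (default 8,
#'   i.e. 08:00).
#' @param H_d Photoperiod length in hours (default 14).  A sample whose
#'   clock hour falls in `[lights_on, lights_on + H_d)` is classified as
#'   day, the rest as night.
#' @param clamp Clamp negative per-sample differentials at zero (default).
#' @param inhibition_threshold Optional temperature (deg C): a day whose
#'   maximum day-time sample meets or exceeds it accumulates nothing.
#' @return An `act_series` data frame, one row per calendar day in the log.
#' @export
accumulate_log <- function(log, T_vd, T_vn, lights_on = 8, H_d = 14,
                           clamp = TRUE, inhibition_threshold = NULL) {
  if (is.character(log)) log <- read_temperature_log(log)
  stopifnot(inherits(log, "temp_log"))
  if (H_d <= 0 || H_d > 24) stop("H_d must be in (0, 24]", call. = FALSE)
  interval <- attr(log, "interval_hours")
  hour <- as.numeric(format(log$timestamp, "%H")) +
    as.numeric(format(log$timestamp, "%M")) / 60
  # day window may wrap midnight
  in_day <- if (lights_on + H_d <= 24) {
    hour >= lights_on & hour < lights_on + H_d
  } else {
    hour >= lights_on | hour < (lights_on + H_d - 24)
  }
  ref <- ifelse(in_day, T_vd, T_vn)
  diff_c <- ref - log$temp_c
  if (clamp) diff_c <- pmax(0, diff_c)
  contrib <- diff_c * interval
  date <- as.Date(format(log$timestamp, "%Y-%m-%d"))
  days <- sort(unique(date))
  inc <- vapply(days, function(d) sum(contrib[date == d]), numeric(1))
  if (!is.null(inhibition_threshold)) {
    day_max <- vapply(days, function(d) {
      v <- log$temp_c[date == d & in_day]
      if (length(v)) max(v) else -Inf
    }, numeric(1))
    inc[day_max >= inhibition_threshold] <- 0
  }
  new_act_series(seq_along(days), inc, index = "full")
}

#' Write an ACT series to CSV
#'
#' Columns `day,increment_c_h,cumulative_c_h`.
#'
#' @param series An `act_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_act_series <- function(series, path) {
  stopifnot(inherits(series, "act_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
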