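# Thermal time (growing degree-days) from hourly temperature records.
#
# Daily mean temperature is the mean over the hours of a day of the
# midpoint between the hourly maximum and minimum, minus a base
# temperature (default 0 degC, the convention for winter wheat in
# temperate climates). GDD is the running sum of daily means, by default
# clamped at zero per day so cold days cannot erode accumulated thermal
# time.

#' Read hourly temperature records from CSV
#'
#' Expects columns `timestamp` (ISO 8601, hourly resolution), `t_max_C`
#' and `t_min_C`. A single `t_C` column is accepted and used for both the
#' hourly maximum and minimum.
#'
#' @param path path to a CSV file.
#' @return a `data.table` with columns `date` (`Date`), `hour` (integer
#'   0--23), `t_max`, `t_min` (degC).
#' @export
read_temperature_csv <- function(path) {
  dt <- data.table::fread(path)
  if (!"timestamp" %in% names(dt)) {
    stop("temperature file must have a 'timestamp' column")
  }
  ts <- as.POSIXct(dt$timestamp, tz = "UTC")
  if (anyNA(ts)) stop("unparseable timestamps in ", path)
  if ("t_C" %in% names(dt) && !all(c("t_max_C", "t_min_C") %in% names(dt))) {
    tmax <- as.numeric(dt$t_C)
    tmin <- as.numeric(dt$t_C)
  } else if (all(c("t_max_C", "t_min_C") %in% names(dt))) {
    tmax <- as.numeric(dt$t_max_C)
    tmin <- as.numeric(dt$t_min_C)
  } else {
    stop("temperature file must have t_max_C/t_min_C or a single t_C column")
  }
  out <- data.table::data.table(
    date = as.Date(ts, tz = "UTC"),
    hour = as.integer(format(ts, "%H", tz = "UTC")),
    t_max = tmax, t_min = tmin
  )
  validate_hourly_temperatures(out)
  out[]
}

validate_hourly_temperatures <- function(dt) {
  stopifnot(all(c("date", "hour", "t_max", "t_min") %in% names(dt)))
  if (nrow(dt) == 0L) stop("empty temperature series")
  if (anyNA(dt$t_max) || anyNA(dt$t_min)) stop("missing temperature values")
  if (any(dt$t_max < dt$t_min)) stop("t_max < t_min in temperature records")
  dup <- dt[, .N, by = .(date, hour)][N > 1L]
  if (nrow(dup) > 0L) {
    stop("duplicated date/hour records, first at ", dup$date[1], " hour ", dup$hour[1])
  }
  invisible(dt)
}

#' Daily mean temperature above a base temperature
#'
#' Mean over the available hours of `(t_max + t_min) / 2`, minus `base_temp`.
#' At most 24 hourly records contribute; if fewer than `min_hours` are
#' present the day is treated as missing data and an error is raised.
#'
#' @param t_max,t_min hourly maximum and minimum temperatures (degC) for one
#'   calendar day, equal length, at most 24 values.
#' @param base_temp base temperature in degC (default 0).
#' @param min_hours minimum number of hourly records required (default 20).
#' @return daily mean temperature above base, in degC.
#' @export
daily_mean_temperature <- function(t_max, t_min, base_temp = 0, min_hours = 20L) {
  if (length(t_max) != length(t_min)) stop("t_max and t_min lengths differ")
  if (length(t_max) == 0L) stop("no hourly records for day: missing data")
  if (length(t_max) > 24L) stop("more than 24 hourly records for one day")
  if (length(t_max) < min_hours) {
    stop("only ", length(t_max), " hourly records present (need >= ", min_hours, ")")
  }
  if (!is.finite(base_temp)) stop("base_temp must be finite")
  mean((t_max + t_min) / 2) - base_temp
}

#' Accumulate growing degree-days over a season
#'
#' Builds a thermal calendar: cumulative GDD per date, zero at the
#' reference date. The reference day itself contributes nothing; day 1 of
#' the accumulation is the first day after the reference. Daily
#' contributions are clamped at zero by default (standard agronomic GDD);
#' with `base_temp = 0` and all temperatures positive, clamping is
#' inconsequential.
#'
#' @param temps hourly temperature `data.table` as returned by
#'   [read_temperature_csv()] (columns `date`, `hour`, `t_max`, `t_min`).
#' @param reference_date first date of the calendar (`Date` or string);
#'   defaults to the earliest date in `temps`.
#' @param base_temp base temperature in degC.
#' @param clamp clamp negative daily means at 0 (default `TRUE`).
#' @param min_hours minimum hourly records per day.
#' @return an object of class `thermal_calendar`: list with `reference_date`,
#'   `base_temp`, `clamp` and a `data.table` `days` with columns `date`,
#'   `daily_mean` and `cumulative_gdd`.
#' @export
accumulate_gdd <- function(temps, reference_date = NULL, base_temp = 0,
                           clamp = TRUE, min_hours = 20L) {
  validate_hourly_temperatures(temps)
  temps <- data.table::as.data.table(temps)
  if (is.null(reference_date)) reference_date <- min(temps$date)
  reference_date <- as.Date(reference_date)
  daily <- temps[, .(daily_mean = daily_mean_temperature(
    t_max, t_min, base_temp = base_temp, min_hours = min_hours
  )), by = date][order(date)]
  span <- seq(min(daily$date), max(daily$date), by = "day")
  missing <- span[!span %in% daily$date]
  if (length(missing) > 0L) {
    stop("gap in daily temperature coverage: ", paste(missing, collapse = ", "))
  }
  if (reference_date < min(daily$date) || reference_date > max(daily$date)) {
    stop("reference_date outside the covered span")
  }
  contrib <- if (clamp) pmax(daily$daily_mean, 0) else daily$daily_mean
  # inclusive running sum, re-anchored so cumulative_gdd[reference] = 0;
  # a day's own contribution is counted at that day, so day 1 of the
  # accumulation is the first day after the reference and differences
  # between two dates are reference-independent
  cum0 <- cumsum(contrib)
  daily[, cumulative_gdd := cum0 - cum0[daily$date == reference_date]]
  structure(
    list(reference_date = reference_date, base_temp = base_temp,
         clamp = clamp, days = daily),
    class = "thermal_calendar"
  )
}

#' @export
print.thermal_calendar <- function(x, ...) {
  cat("<thermal_calendar> ", as.character(min(x$days$date)), " .. ",
      as.character(max(x$days$date)),
      " | reference ", as.character(x$reference_date),
      " | baseT ", x$base_temp, " degC",
      " | final GDD ", round(max(x$days$cumulative_gdd), 1), " degC days\n",
      sep = "")
  invisible(x)
}

#' Thermal time elapsed between heading and a query date
#'
#' @param calendar a [accumulate_gdd()] result.
#' @param heading_date,query_date dates within the calendar span,
#'   `heading_date <= query_date`.
#' @return thermal time in degC days (vectorised over `query_date`).
#' @export
thermal_time_after_heading <- function(calendar, heading_date, query_date) {
  stopifnot(inherits(calendar, "thermal_calendar"))
  heading_date <- as.Date(heading_date)
  query_date <- as.Date(query_date)
  days <- calendar$days
  lookup <- function(d) {
    i <- match(d, days$date)
    if (anyNA(i)) {
      stop("date(s) outside calendar span: ",
           paste(d[is.na(i)], collapse = ", "))
    }
    days$cumulative_gdd[i]
  }
  if (any(query_date < heading_date)) {
    stop("query date precedes heading date; no pre-heading extrapolation")
  }
  lookup(query_date) - lookup(heading_date)
}

#' Write a thermal calendar to CSV
#'
#' Columns: `date`, `daily_mean_C`, `cumulative_gdd_Cd`.
#'
#' @param calendar a `thermal_calendar`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_thermal_calendar <- function(calendar, path) {
  stopifnot(inherits(calendar, "thermal_calendar"))
  out <- data.table::data.table(
    date = as.character(calendar$days$date),
    daily_mean_C = calendar$days$daily_mean,
    cumulative_gdd_Cd = calendar$days$cumulative_gdd
  )
  data.table::fwrite(out, path, nThread = 1L)
  invisible(path)
}
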