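# Shared fixture builders (all generated in code; no stored data).

# hourly series with given per-day (max, min) pairs, 24 h per day
hourly_series <- function(daily_max, daily_min, start = "2016-06-01") {
  stopifnot(length(daily_max) == length(daily_min))
  dates <- seq(as.Date(start), by = "day", length.out = length(daily_max))
  data.table::data.table(
    date = rep(dates, each = 24L),
    hour = rep(0:23, times = length(dates)),
    t_max = rep(daily_max, each = 24L),
    t_min = rep(daily_min, each = 24L)
  )
}

# constant-mean hourly series: each day's (max+min)/2 averages to `mean_daily`
constant_temp_series <- function(mean_daily, n_days, start = "2016-06-01") {
  hourly_series(rep(mean_daily, n_days), rep(mean_daily, n_days), start)
}

# tiny collection: `values` is a matrix plots x wavelengths
tiny_collection <- function(wavelength, values, plot_ids = NULL, dates = NULL) {
  n <- nrow(values)
  spectra_collection(
    data.frame(
      plot_id = if (is.null(plot_ids)) sprintf("p%02d", seq_len(n)) else plot_ids,
      date = if (is.null(dates)) as.Date("2016-06-15") + seq_len(n) else dates
    ),
    wavelength, values
  )
}

# mixed-endmember collection over a greenness sequence on a reduced grid
mixing_collection <- function(g_values, grid = 350:900, plot_id = "p1") {
  em <- make_endmembers(grid)
  values <- t(vapply(g_values, function(g) g * em$green + (1 - g) * em$senescent,
                     numeric(length(grid))))
  tiny_collection(grid, values, plot_ids = rep(plot_id, length(g_values)),
                  dates = as.Date("2016-06-01") + seq_along(g_values))
}
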