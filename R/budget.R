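#' Daily daytime summaries of a logger series
#'
#' Reduces a 30-min (or other cadence) surface-temperature series to one
#' record per nest per calendar day: the daytime minimum, maximum and range,
#' the number of intervals observed, and a completeness flag. The daily
#' minimum corresponds to the pre-dawn/dawn temperature, and the range
#' captures how strongly a nest warms during the day. A day is complete when
#' the observed daytime intervals reach `coverage_threshold` of the number
#' expected from the cadence and day length; incomplete days (logger battery
#' failure, displaced probes) are flagged so model fits can exclude them.
#'
#' @param series tibble with `nest_id`, `timestamp` (POSIXct), `temp_c`.
#' @param site_latitude latitude in decimal degrees for the daylight mask.
#' @param coverage_threshold completeness fraction (default 0.9).
#' @return a tibble with one row per nest-day: `nest_id`, `date`,
#'   `n_intervals_observed`, `daytime_min`, `daytime_max`, `daytime_range`,
#'   `complete`.
#' @export
summarize_daily <- function(series, site_latitude = -32.3,
                            coverage_threshold = 0.9) {
  stopifnot(is.data.frame(series), nrow(series) > 0,
            all(c("nest_id", "timestamp", "temp_c") %in% names(series)))
  cadence <- infer_cadence(series$timestamp)
  day <- daytime_mask(series$timestamp, site_latitude)
  df <- series[day & is.finite(series$temp_c), , drop = FALSE]
  df$date <- as.Date(df$timestamp, tz = "UTC")
  out <- df |>
    dplyr::group_by(.data$nest_id, .data$date) |>
    dplyr::summarise(
      n_intervals_observed = dplyr::n(),
      daytime_min = min(.data$temp_c),
      daytime_max = max(.data$temp_c),
      .groups = "drop"
    ) |>
    dplyr::mutate(daytime_range = .data$daytime_max - .data$daytime_min)
  # expected daytime ticks per date from a full-day grid at the cadence
  expected <- expected_daytime_intervals(unique(out$date), cadence,
                                         site_latitude)
  out <- dplyr::left_join(out, expected, by = "date")
  out$complete <- out$n_intervals_observed >=
    coverage_threshold * out$n_expected
  dplyr::select(out, "nest_id", "date", "n_intervals_observed",
                "daytime_min", "daytime_max", "daytime_range", "complete")
}

# median spacing of the timestamp grid, in minutes
infer_cadence <- function(timestamps) {
  d <- diff(sort(unique(as.numeric(timestamps)))) / 60
  if (length(d) == 0) return(30)
  stats::median(d)
}

expected_daytime_intervals <- function(dates, cadence, site_latitude) {
  ticks_per_day <- round(1440 / cadence)
  hours <- (seq_len(ticks_per_day) - 1) * cadence / 60
  purrr::map_dfr(dates, function(d) {
    doy <- as.integer(strftime(d, "%j"))
    tibble::tibble(
      date = d,
      n_expected = sum(solar_sin_elevation(doy, hours, site_latitude) > 0)
    )
  })
}

#' Daily hours available for activity within a temperature window
#'
#' Counts, for each nest-day, the observed logger intervals whose temperature
#' lies inside `[lo, hi]` (inclusive at both ends, since the thresholds are
#' defined by activity observed at those temperatures) and converts the count
#' to hours. By default intervals are counted over the full 24-hour day;
#' night temperatures below the lower threshold contribute zero naturally.
#' Missing intervals contribute zero hours and the day inherits the
#' completeness flag of [summarize_daily()].
#'
#' @param series tibble with `nest_id`, `timestamp`, `temp_c`.
#' @param lo,hi window bounds in degrees C (`lo <= hi`), e.g. an emergence or
#'   optimal window from [performance_window()].
#' @param site_latitude latitude for the completeness computation (and the
#'   daytime mask when `scope = "daytime"`).
#' @param scope count over the `"full-day"` (default) or `"daytime"` only.
#' @param coverage_threshold completeness fraction (default 0.9).
#' @return a tibble with `nest_id`, `date`, `n_in_window`, `hours`,
#'   `complete`.
#' @export
available_hours <- function(series, lo, hi, site_latitude = -32.3,
                            scope = c("full-day", "daytime"),
                            coverage_threshold = 0.9) {
  scope <- match.arg(scope)
  if (!is.finite(lo) || !is.finite(hi) || lo > hi) {
    stop("window bounds must satisfy lo <= hi", call. = FALSE)
  }
  stopifnot(is.data.frame(series), nrow(series) > 0)
  cadence <- infer_cadence(series$timestamp)
  keep <- is.finite(series$temp_c)
  if (scope == "daytime") {
    keep <- keep & daytime_mask(series$timestamp, site_latitude)
  }
  df <- series[keep, , drop = FALSE]
  df$date <- as.Date(df$timestamp, tz = "UTC")
  counts <- df |>
    dplyr::group_by(.data$nest_id, .data$date) |>
    dplyr::summarise(
      n_in_window = sum(.data$temp_c >= lo & .data$temp_c <= hi),
      .groups = "drop"
    ) |>
    dplyr::mutate(hours = .data$n_in_window * cadence / 60)
  daily <- summarize_daily(series, site_latitude, coverage_threshold)
  dplyr::left_join(
    counts,
    dplyr::select(daily, "nest_id", "date", "complete"),
    by = c("nest_id", "date")
  ) |>
    dplyr::mutate(complete = !is.na(.data$complete) & .data$complete)
}

#' Seasonal apex and base of the daily activity-hours trend
#'
#' Fits a cyclic seasonal spline of day-of-year to each nest's daily hours
#' and reports the maximum (summer apex) and minimum (winter base) of the
#' fitted trend. These per-nest summaries are the inputs to the behavioural
#' compensation analysis.
#'
#' @param budgets output of [available_hours()] (complete days are used).
#' @param k seasonal basis dimension (default 8).
#' @return a tibble with `nest_id`, `hours_summer`, `hours_winter`.
#' @export
seasonal_hours_summary <- function(budgets, k = 8) {
  budgets <- budgets[budgets$complete, , drop = FALSE]
  budgets$doy <- as.integer(strftime(budgets$date, "%j"))
  purrr::map_dfr(split(budgets, budgets$nest_id), function(d) {
    fit <- fit_additive(d, "hours",
                        smooths = list(smooth_spec("doy", k = k, basis = "cc")),
                        knots = list(doy = c(0.5, 366)))
    grid <- data.frame(doy = 1:365)
    pred <- predict(fit, grid)
    tibble::tibble(
      nest_id = d$nest_id[1],
      hours_summer = max(pred),
      hours_winter = max(0, min(pred))
    )
  })
}
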