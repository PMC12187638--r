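#' Nest microclimate profiles
#'
#' Builds the table of per-nest generative parameters used by the synthetic
#' data generators. Each nest is described by how strongly its surface warms
#' above the shared night-time baseline (`exposure_amplitude`, set by shading),
#' how much that warming is modulated seasonally, its size in entrance holes,
#' and a log10-scale foraging-effort offset used when generating trail counts.
#'
#' @param nest_id character labels, one per nest.
#' @param exposure_amplitude peak diurnal warming above the common baseline
#'   (degrees C, `>= 0`), one value per nest.
#' @param seasonal_amplitude seasonal modulation of the diurnal warming
#'   (degrees C); positive values warm summers relative to winters.
#' @param size_holes nest size as a count of entrance holes (`>= 1`).
#' @param trail_propensity per-nest offset on the log10 trail-count scale.
#' @return a tibble with one row per nest.
#' @seealso [default_nest_profiles()] for a ready-made study-like set.
#' @export
nest_profiles <- function(nest_id, exposure_amplitude,
                          seasonal_amplitude = 6,
                          size_holes = 30,
                          trail_propensity = 0) {
  if (length(nest_id) == 0) stop("at least one nest is required", call. = FALSE)
  if (anyDuplicated(nest_id)) stop("`nest_id` must be unique", call. = FALSE)
  out <- tibble::tibble(
    nest_id = as.character(nest_id),
    exposure_amplitude = as.numeric(exposure_amplitude),
    seasonal_amplitude = as.numeric(seasonal_amplitude),
    size_holes = as.integer(size_holes),
    trail_propensity = as.numeric(trail_propensity)
  )
  if (any(out$exposure_amplitude < 0)) {
    stop("`exposure_amplitude` must be non-negative", call. = FALSE)
  }
  if (any(out$size_holes < 1)) stop("`size_holes` must be >= 1", call. = FALSE)
  out
}

#' Default nest profiles emulating the focal study nests
#'
#' Deterministic profiles spanning sheltered to exposed placements. The
#' exposure amplitudes span 12-24 degrees C so that, on the default baseline,
#' the most sheltered nest reaches winter daily maxima around 15-20 degrees C
#' and the most exposed around 25-30 degrees C, with summer maxima approaching
#' the upper 40s for the most exposed placement.
#'
#' @param n number of nests (default 6, the number of logger-equipped nests).
#' @return a tibble of nest profiles (see [nest_profiles()]).
#' @export
default_nest_profiles <- function(n = 6) {
  stopifnot(n >= 1)
  roman <- as.character(utils::as.roman(seq_len(n)))
  sizes <- round(seq(6, 58, length.out = max(n, 2)))[seq_len(n)]
  # interleave sizes so size is not confounded with exposure
  sizes <- sizes[order(seq_len(n) %% 2, decreasing = TRUE)]
  nest_profiles(
    nest_id = paste0("N", roman),
    exposure_amplitude = seq(12, 24, length.out = n),
    seasonal_amplitude = 6,
    size_holes = pmax(1L, sizes),
    trail_propensity = seq(-0.2, 0.2, length.out = n)
  )
}

#' Simulation configuration
#'
#' Shared settings for the microclimate generator: the site, sampling window
#' and cadence, the common baseline temperature cycle, and the AR(1) noise on
#' the logger grid.
#'
#' @param date_range a length-2 `Date` (or coercible) vector, first day and
#'   last day inclusive.
#' @param cadence sampling interval in minutes; must divide 1440 (default 30,
#'   the logger cadence).
#' @param site_latitude decimal degrees (default -32.3, mid-latitude
#'   New South Wales).
#' @param base_temp annual mean of the shared pre-dawn baseline (degrees C).
#' @param base_seasonal_amplitude seasonal swing of the baseline (degrees C).
#' @param noise_sd stationary standard deviation of the AR(1) noise
#'   (degrees C).
#' @param noise_autocorrelation lag-1 autocorrelation on the sampling grid, in
#'   `[0, 1)`.
#' @param seed integer seed driving all generator randomness.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(date_range = as.Date(c("2019-01-01", "2020-12-31")),
                       cadence = 30,
                       site_latitude = -32.3,
                       base_temp = 10,
                       base_seasonal_amplitude = 7,
                       noise_sd = 1.5,
                       noise_autocorrelation = 0.8,
                       seed = 1L) {
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || anyNA(date_range) ||
      date_range[2] < date_range[1]) {
    stop("`date_range` must be two ascending dates", call. = FALSE)
  }
  if (cadence <= 0 || 1440 %% cadence != 0) {
    stop("`cadence` must be a positive divisor of 1440 minutes", call. = FALSE)
  }
  if (noise_autocorrelation < 0 || noise_autocorrelation >= 1) {
    stop("`noise_autocorrelation` must lie in [0, 1)", call. = FALSE)
  }
  if (abs(site_latitude) > 66.5) {
    stop("`site_latitude` must lie within [-66.5, 66.5]", call. = FALSE)
  }
  structure(
    list(
      date_range = date_range, cadence = cadence,
      site_latitude = site_latitude, base_temp = base_temp,
      base_seasonal_amplitude = base_seasonal_amplitude,
      noise_sd = noise_sd, noise_autocorrelation = noise_autocorrelation,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Seasonal index
#'
#' Cosine seasonal score for a day of year: +1 in mid-January (southern-
#' hemisphere summer), -1 in mid-July. Used both by the generator (seasonal
#' modulation) and as the random-slope covariate in the variance models.
#'
#' @param doy integer day of year (1-366).
#' @return numeric in `[-1, 1]`.
#' @export
seasonal_index <- function(doy) {
  cos(2 * pi * (doy - 15) / 365.25)
}

# deterministic surface temperature for one nest at given doy/hour vectors
nest_deterministic_temp <- function(doy, hour, profile, config) {
  baseline <- config$base_temp +
    config$base_seasonal_amplitude * seasonal_index(doy)
  ss <- sunrise_sunset(doy, config$site_latitude)
  amp <- pmax(0, profile$exposure_amplitude +
                profile$seasonal_amplitude * seasonal_index(doy))
  frac <- (hour - ss$sunrise) / (ss$sunset - ss$sunrise)
  bump <- ifelse(frac > 0 & frac < 1, amp * sin(pi * frac), 0)
  baseline + bump
}

#' Simulate nest surface-temperature logger series
#'
#' Generates one surface-temperature series per nest on a shared timestamp
#' grid. The deterministic component is a shared baseline (annual sinusoid)
#' plus a nest-specific half-sine diurnal bump confined to daylight, so all
#' nests share an identical pre-dawn minimum each day while differing in
#' daytime warming, mirroring loggers on nests that cool overnight to a common
#' temperature. AR(1) noise on the sampling grid is added per nest.
#'
#' @param profiles a tibble from [nest_profiles()].
#' @param config a [sim_config()].
#' @return a tibble with columns `nest_id`, `timestamp` (POSIXct, local
#'   standard time stored as UTC), `temp_c`.
#' @export
simulate_temperature_series <- function(profiles, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    stop("`profiles` must be a non-empty nest-profile table", call. = FALSE)
  }
  ts <- seq(
    as.POSIXct(paste(config$date_range[1], "00:00:00"), tz = "UTC"),
    as.POSIXct(paste(config$date_range[2], "23:59:59"), tz = "UTC"),
    by = config$cadence * 60
  )
  lt <- as.POSIXlt(ts)
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60
  n <- length(ts)
  phi <- config$noise_autocorrelation
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  out <- purrr::map_dfr(seq_len(nrow(profiles)), function(j) {
    det <- nest_deterministic_temp(doy, hour, profiles[j, ], config)
    noise <- if (config$noise_sd > 0) {
      e <- stats::rnorm(n, 0, config$noise_sd * sqrt(1 - phi^2))
      x <- numeric(n)
      x[1] <- stats::rnorm(1, 0, config$noise_sd)
      for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
      x
    } else {
      # keep the RNG stream aligned whether or not noise is on
      rep(0, n)
    }
    tibble::tibble(
      nest_id = profiles$nest_id[j],
      timestamp = ts,
      temp_c = det + noise
    )
  })
  attr(out, "config") <- config
  out
}

# save/restore RNG state so generators are seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Activity curve specification (generator ground truth)
#'
#' Parameters of the true thermal performance curve that the activity
#' generator samples from: expected activity is a Gaussian-shaped unimodal
#' curve of temperature, and the probability that any workers are out at all
#' is a double logistic (a rising and a falling logistic multiplied), giving
#' tails at both temperature extremes.
#'
#' @param peak_temp temperature of maximal activity (degrees C).
#' @param curve_width Gaussian spread of the mean-activity curve (degrees C).
#' @param max_rate expected workers per count at the peak.
#' @param presence_midpoints length-2: lower and upper logistic midpoints
#'   (degrees C); must bracket `peak_temp`.
#' @param presence_steepness logistic steepness (per degree C).
#' @return a list of class `true_curve_spec`.
#' @export
true_curve_spec <- function(peak_temp = 30, curve_width = 5, max_rate = 20,
                            presence_midpoints = c(17, 42),
                            presence_steepness = 0.8) {
  if (curve_width <= 0) stop("`curve_width` must be positive", call. = FALSE)
  if (max_rate <= 0) stop("`max_rate` must be positive", call. = FALSE)
  if (length(presence_midpoints) != 2 ||
      !(presence_midpoints[1] < peak_temp && peak_temp < presence_midpoints[2])) {
    stop("presence midpoints must bracket `peak_temp`", call. = FALSE)
  }
  structure(
    list(
      peak_temp = peak_temp, curve_width = curve_width, max_rate = max_rate,
      presence_midpoints = presence_midpoints,
      presence_steepness = presence_steepness
    ),
    class = "true_curve_spec"
  )
}

#' True presence probability and mean-activity curve
#'
#' Evaluate the generator's ground-truth curves at given temperatures.
#'
#' @param curve a [true_curve_spec()].
#' @param temp temperatures (degrees C).
#' @return `true_presence()`: probability in (0, 1); `true_activity()`: the
#'   unimodal relative activity in (0, 1]; `true_combined()`: expected
#'   observed count, presence times `max_rate` times relative activity.
#' @export
true_presence <- function(curve, temp) {
  s <- curve$presence_steepness
  stats::plogis(s * (temp - curve$presence_midpoints[1])) *
    stats::plogis(s * (curve$presence_midpoints[2] - temp))
}

#' @rdname true_presence
#' @export
true_activity <- function(curve, temp) {
  exp(-(temp - curve$peak_temp)^2 / (2 * curve$curve_width^2))
}

#' @rdname true_presence
#' @export
true_combined <- function(curve, temp) {
  true_presence(curve, temp) * curve$max_rate * true_activity(curve, temp)
}

#' Simulate hourly activity observations
#'
#' Samples the temperature series at hourly daylight times on the survey dates
#' (by default one mid-summer and one mid-winter day, as in a dawn-to-dusk
#' census) and draws activity from the ground-truth curve: worker counts come
#' from presence (double logistic in temperature) times a Poisson abundance
#' whose mean follows the unimodal curve scaled by nest size; swarm speeds are
#' Gaussian around the unimodal curve when workers emerge.
#'
#' @param series tibble from [simulate_temperature_series()].
#' @param curve a [true_curve_spec()].
#' @param profiles the nest-profile tibble used to generate `series`.
#' @param dates survey dates (`Date`); default picks 15 January and 15 July of
#'   the first year covered by the series.
#' @param response `"count"` for foraging worker counts or `"speed"` for
#'   defensive swarm speeds.
#' @param seed integer seed.
#' @param size_ref,size_coef nest-size effect: the Poisson mean is multiplied
#'   by `exp(size_coef * (size_holes - size_ref))` (defaults 30 holes and 0.04
#'   per hole).
#' @param speed_max,speed_sd swarm-speed scale (mm/s) and Gaussian noise.
#' @param site_latitude latitude for the daylight schedule; taken from the
#'   series config when available.
#' @return a tibble of activity observations with columns `nest_id`,
#'   `datetime`, `surface_temp`, `worker_count` or (`swarm_speed`, `emerged`),
#'   `light`, `wind`, `nest_size`, `time_of_day`.
#' @export
simulate_activity <- function(series, curve, profiles, dates = NULL,
                              response = c("count", "speed"), seed = 1L,
                              size_ref = 30, size_coef = 0.04,
                              speed_max = 16, speed_sd = 2,
                              site_latitude = NULL) {
  response <- match.arg(response)
  stopifnot(inherits(curve, "true_curve_spec"))
  cfg <- attr(series, "config")
  if (is.null(site_latitude)) {
    site_latitude <- if (!is.null(cfg)) cfg$site_latitude else -32.3
  }
  all_dates <- as.Date(series$timestamp, tz = "UTC")
  if (is.null(dates)) {
    yr <- format(min(all_dates), "%Y")
    dates <- as.Date(c(paste0(yr, "-01-15"), paste0(yr, "-07-15")))
    dates <- dates[dates %in% all_dates]
    if (length(dates) == 0) dates <- min(all_dates)
  }
  if (!all(dates %in% all_dates)) {
    stop("sampling dates fall outside the series range", call. = FALSE)
  }
  # hourly on-the-hour schedule within daylight, dawn through dusk
  sched <- purrr::map_dfr(dates, function(d) {
    doy <- as.integer(strftime(d, "%j"))
    ss <- sunrise_sunset(doy, site_latitude)
    hours <- seq(ceiling(ss$sunrise), floor(ss$sunset))
    tibble::tibble(
      datetime = as.POSIXct(paste(d, sprintf("%02d:00:00", hours)), tz = "UTC")
    )
  })
  obs <- dplyr::inner_join(series, sched, by = c("timestamp" = "datetime"))
  if (nrow(obs) == 0) stop("schedule outside series range", call. = FALSE)
  obs <- dplyr::left_join(
    obs,
    dplyr::select(profiles, "nest_id", "size_holes"),
    by = "nest_id"
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(obs)
  temp <- obs$temp_c
  p <- true_presence(curve, temp)
  present <- stats::rbinom(n, 1, p)
  lt <- as.POSIXlt(obs$timestamp)
  tod <- lt$hour + lt$min / 60
  sin_elev <- pmax(0, solar_sin_elevation(lt$yday + 1, tod, site_latitude))
  out <- tibble::tibble(
    nest_id = obs$nest_id,
    datetime = obs$timestamp,
    surface_temp = temp,
    light = round(100000 * sin_elev),
    wind = round(abs(stats::rnorm(n, 2, 1)), 1),
    nest_size = obs$size_holes,
    time_of_day = tod
  )
  if (response == "count") {
    lambda <- curve$max_rate * true_activity(curve, temp) *
      exp(size_coef * (obs$size_holes - size_ref))
    out$worker_count <- as.integer(present * stats::rpois(n, lambda))
  } else {
    mu <- speed_max * true_activity(curve, temp)
    out$emerged <- present == 1
    out$swarm_speed <- ifelse(out$emerged,
                              pmax(0, stats::rnorm(n, mu, speed_sd)), 0)
  }
  attr(out, "curve") <- curve
  out
}

#' Simulate annual nest surveys
#'
#' Generates yearly entrance-hole counts following a flat, linear or quadratic
#' trend per nest, plus trail counts on the log10 scale with known per-nest
#' effort offsets, so that the effort-standardization and growth-model stages
#' have a known ground truth. Trend magnitudes default to values of the order
#' seen in long-term meat-ant censuses (declines of a few holes per year;
#' hump-shaped growth-then-decline for the quadratic shape).
#'
#' @param profiles nest-profile tibble; `size_holes` is the year-0 size and
#'   `trail_propensity` the per-nest log10 effort offset.
#' @param trend character vector (recycled over nests) of
#'   `"flat"`, `"linear"`, `"quadratic"`, or a tibble with columns `nest_id`,
#'   `slope`, `quad` for full control.
#' @param years number of survey years (`>= 3`).
#' @param start_year first survey year.
#' @param noise_frac size noise sd as a fraction of each nest's mean
#'   trajectory size (default 0.1).
#' @param slope_linear,slope_quad,quad_coef default trend coefficients
#'   (holes/year and holes/year^2).
#' @param trail_intercept,trail_size_coef,trail_noise_sd trail-count model:
#'   `log10(trails) = intercept + size_coef * holes + propensity + noise`.
#' @param seed integer seed.
#' @return a tibble with columns `nest_id`, `year`, `entrance_holes`,
#'   `n_foraging_trails`, `n_tree_trails`, `n_connection_trails`, plus the
#'   generating `trend` label.
#' @export
simulate_surveys <- function(profiles, trend = "flat", years = 10,
                             start_year = 2015, noise_frac = 0.1,
                             slope_linear = -2.5, slope_quad = 4,
                             quad_coef = -0.6,
                             trail_intercept = 0.15, trail_size_coef = 0.01,
                             trail_noise_sd = 0.08, seed = 1L) {
  if (years < 3) stop("`years` must be at least 3", call. = FALSE)
  n_nest <- nrow(profiles)
  if (is.character(trend)) {
    shape <- rep(trend, length.out = n_nest)
    if (!all(shape %in% c("flat", "linear", "quadratic"))) {
      stop("trend must be flat, linear or quadratic", call. = FALSE)
    }
    trend <- tibble::tibble(
      nest_id = profiles$nest_id,
      trend = shape,
      slope = dplyr::case_when(
        shape == "flat" ~ 0,
        shape == "linear" ~ slope_linear,
        shape == "quadratic" ~ slope_quad
      ),
      quad = ifelse(shape == "quadratic", quad_coef, 0)
    )
  } else {
    stopifnot(all(c("nest_id", "slope", "quad") %in% names(trend)))
    if (!"trend" %in% names(trend)) {
      trend$trend <- ifelse(trend$quad != 0, "quadratic",
                            ifelse(trend$slope != 0, "linear", "flat"))
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t <- seq_len(years) - 1
  purrr::map_dfr(seq_len(n_nest), function(j) {
    pr <- profiles[j, ]
    tr <- trend[trend$nest_id == pr$nest_id, ]
    det <- pr$size_holes + tr$slope * t + tr$quad * t^2
    det <- pmax(det, 1)
    sd_size <- noise_frac * mean(det)
    holes <- pmax(1L, as.integer(round(det + stats::rnorm(years, 0, sd_size))))
    log_trails <- trail_intercept + trail_size_coef * holes +
      pr$trail_propensity + stats::rnorm(years, 0, trail_noise_sd)
    total <- pmax(0L, as.integer(round(10^log_trails)))
    tree <- stats::rbinom(years, total, 0.5)
    tibble::tibble(
      nest_id = pr$nest_id,
      year = start_year + t,
      entrance_holes = holes,
      n_foraging_trails = total - tree,
      n_tree_trails = tree,
      n_connection_trails = stats::rpois(years, 0.3),
      trend = tr$trend
    )
  })
}

#' Simulate swarm-onset data for the change-point model
#'
#' Two-segment ground truth: swarm speed is zero (plus noise) below a
#' nest-specific threshold temperature and rises linearly above it; nest
#' thresholds scatter around a population mean. Used to validate the
#' hierarchical change-point sampler.
#'
#' @param n_nests,n_per_nest design size.
#' @param tau_pop population-mean onset temperature (degrees C).
#' @param tau_sd between-nest threshold sd (degrees C).
#' @param slope speed increase per degree above threshold.
#' @param sigma residual sd of speed.
#' @param temp_range observation temperatures are uniform over this range.
#' @param seed integer seed.
#' @return a tibble with `nest_id`, `surface_temp`, `swarm_speed`, and the
#'   generating `tau_true` per nest.
#' @export
simulate_swarm_onset <- function(n_nests = 3, n_per_nest = 30, tau_pop = 13,
                                 tau_sd = 0.5, slope = 1, sigma = 1.5,
                                 temp_range = c(5, 45), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tau_j <- stats::rnorm(n_nests, tau_pop, tau_sd)
  purrr::map_dfr(seq_len(n_nests), function(j) {
    temp <- stats::runif(n_per_nest, temp_range[1], temp_range[2])
    mu <- slope * pmax(0, temp - tau_j[j])
    tibble::tibble(
      nest_id = paste0("N", j),
      surface_temp = temp,
      swarm_speed = mu + stats::rnorm(n_per_nest, 0, sigma),
      tau_true = tau_j[j]
    )
  })
}
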