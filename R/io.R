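#' Read a nest surface-temperature logger CSV
#'
#' Expected columns: `nest_id`, `timestamp` (ISO-8601), `temp_c`. Rows with
#' unparseable timestamps, non-finite temperatures, or duplicate
#' (nest, timestamp) keys are rejected; the rejected rows and their reasons
#' are attached as the `validation` attribute and summarized in a message.
#'
#' @param path CSV file path.
#' @return a tibble of accepted records, sorted by nest and time, with a
#'   `validation` attribute (tibble of `row`, `reason`).
#' @export
read_logger_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("nest_id", "timestamp", "temp_c")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    message("empty input: 0 logger records")
    out <- tibble::tibble(nest_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          temp_c = numeric())
    attr(out, "validation") <- tibble::tibble(row = integer(), reason = character())
    return(out)
  }
  ts <- parse_iso8601(raw$timestamp)
  temp <- suppressWarnings(as.numeric(raw$temp_c))
  reasons <- rep(NA_character_, nrow(raw))
  reasons[is.na(ts)] <- "unparseable timestamp"
  reasons[is.na(reasons) & !is.finite(temp)] <- "non-finite temperature"
  key <- paste(raw$nest_id, as.numeric(ts))
  dup <- duplicated(key) & is.na(reasons)
  reasons[dup] <- "duplicate (nest, timestamp) key"
  keep <- is.na(reasons)
  out <- tibble::tibble(nest_id = raw$nest_id[keep], timestamp = ts[keep],
                        temp_c = temp[keep])
  out <- dplyr::arrange(out, .data$nest_id, .data$timestamp)
  rej <- tibble::tibble(row = which(!keep), reason = reasons[!keep])
  attr(out, "validation") <- rej
  message(nrow(out), " logger records accepted, ", nrow(rej), " rejected")
  out
}

#' Read an activity-observation CSV
#'
#' Expected columns: `nest_id`, `datetime` (ISO-8601), `surface_temp`, and
#' exactly one of `worker_count` / `swarm_speed` per row, plus optional
#' `light`, `wind`, `nest_size`. Rows violating the one-response rule, with
#' unparseable datetimes, or with surface temperatures outside [-10, 70]
#' degrees C are rejected with reasons.
#'
#' @param path CSV file path.
#' @return a tibble of accepted observations with a `validation` attribute.
#' @export
read_activity_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("nest_id", "datetime", "surface_temp")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  has_count <- "worker_count" %in% names(raw)
  has_speed <- "swarm_speed" %in% names(raw)
  if (!has_count && !has_speed) {
    stop("need a `worker_count` or `swarm_speed` column", call. = FALSE)
  }
  if (nrow(raw) == 0) {
    message("empty input: 0 activity records")
    out <- tibble::tibble()
    attr(out, "validation") <- tibble::tibble(row = integer(), reason = character())
    return(out)
  }
  dt <- parse_iso8601(raw$datetime)
  temp <- suppressWarnings(as.numeric(raw$surface_temp))
  count <- if (has_count) suppressWarnings(as.numeric(raw$worker_count)) else rep(NA_real_, nrow(raw))
  speed <- if (has_speed) suppressWarnings(as.numeric(raw$swarm_speed)) else rep(NA_real_, nrow(raw))
  reasons <- rep(NA_character_, nrow(raw))
  reasons[is.na(dt)] <- "unparseable datetime"
  reasons[is.na(reasons) & (!is.finite(temp) | temp < -10 | temp > 70)] <-
    "surface temperature outside [-10, 70]"
  both <- !is.na(count) & !is.na(speed)
  neither <- is.na(count) & is.na(speed)
  reasons[is.na(reasons) & (both | neither)] <-
    "exactly one of worker_count / swarm_speed required"
  keep <- is.na(reasons)
  out <- tibble::tibble(
    nest_id = raw$nest_id[keep],
    datetime = dt[keep],
    surface_temp = temp[keep]
  )
  if (has_count) out$worker_count <- as.integer(count[keep])
  if (has_speed) out$swarm_speed <- speed[keep]
  for (v in c("light", "wind", "nest_size", "time_of_day")) {
    if (v %in% names(raw)) out[[v]] <- suppressWarnings(as.numeric(raw[[v]][keep]))
  }
  if (!"time_of_day" %in% names(out)) {
    lt <- as.POSIXlt(out$datetime)
    out$time_of_day <- lt$hour + lt$min / 60
  }
  rej <- tibble::tibble(row = which(!keep), reason = reasons[!keep])
  attr(out, "validation") <- rej
  message(nrow(out), " activity records accepted, ", nrow(rej), " rejected")
  out
}

#' Read an annual survey CSV
#'
#' Expected columns: `nest_id`, `year`, `entrance_holes`,
#' `n_foraging_trails`, `n_tree_trails`, `n_connection_trails`. Rows with
#' negative counts or duplicate (nest, year) keys are rejected.
#'
#' @param path CSV file path.
#' @return a tibble of accepted records with a `validation` attribute.
#' @export
read_survey_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    nest_id = "c", .default = "d"
  ), progress = FALSE)
  need <- c("nest_id", "year", "entrance_holes", "n_foraging_trails",
            "n_tree_trails", "n_connection_trails")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- as.matrix(raw[, need[-1]])
  reasons <- rep(NA_character_, nrow(raw))
  bad <- rowSums(!is.finite(counts) | counts < 0) > 0
  reasons[bad] <- "negative or missing count"
  dup <- duplicated(paste(raw$nest_id, raw$year)) & is.na(reasons)
  reasons[dup] <- "duplicate (nest, year) key"
  keep <- is.na(reasons)
  out <- raw[keep, need]
  out$year <- as.integer(out$year)
  out$entrance_holes <- as.integer(out$entrance_holes)
  rej <- tibble::tibble(row = which(!keep), reason = reasons[!keep])
  attr(out, "validation") <- rej
  message(nrow(out), " survey records accepted, ", nrow(rej), " rejected")
  out
}

#' Pipeline configuration
#'
#' Settings for [run_pipeline()]. Either the three input paths or a
#' `simulate` block must be supplied (exactly one).
#'
#' @param activity_path,logger_path,survey_path input CSVs (see the readers).
#' @param simulate a list of overrides for the synthetic generators (fields
#'   of [sim_config()] plus `n_nests`), or `TRUE` for defaults.
#' @param site_latitude decimal degrees.
#' @param fraction optimal-window fraction in (0, 1).
#' @param grid_step curve-evaluation grid in degrees C.
#' @param coverage_threshold daily completeness rule.
#' @param n_sim_rlrt simulated statistics per RLRT.
#' @param mcmc list with `iterations`, `warmup`, `chains` for the
#'   change-point model.
#' @param seed master seed for every stochastic stage.
#' @param output_dir directory for the report bundle.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(activity_path = NULL, logger_path = NULL,
                            survey_path = NULL, simulate = NULL,
                            site_latitude = -32.3, fraction = 0.90,
                            grid_step = 0.1, coverage_threshold = 0.9,
                            n_sim_rlrt = 199,
                            mcmc = list(iterations = 1000, warmup = 500,
                                        chains = 2),
                            seed = 1L, output_dir = tempfile("nestherm_run_")) {
  have_paths <- !is.null(activity_path) || !is.null(logger_path) ||
    !is.null(survey_path)
  have_sim <- !is.null(simulate) && !isFALSE(simulate)
  if (have_paths == have_sim) {
    stop("supply exactly one of input paths or a simulate block",
         call. = FALSE)
  }
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(activity_path = activity_path, logger_path = logger_path,
         survey_path = survey_path,
         simulate = if (isTRUE(simulate)) list() else simulate,
         site_latitude = site_latitude, fraction = fraction,
         grid_step = grid_step, coverage_threshold = coverage_threshold,
         n_sim_rlrt = n_sim_rlrt, mcmc = mcmc, seed = as.integer(seed),
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full thermal-activity analysis pipeline
#'
#' Orchestrates the analysis end to end: load or simulate the three input
#' tables; fit the foraging hurdle curve and the swarm curve and extract
#' peak, optimal and emergence windows; convert the logger series into daily
#' available hours for each window; rank the nested random-effect models of
#' daily minima, ranges and hours (BIC + RLRT); standardize foraging effort,
#' test compensation, and select nest-growth models. All randomness flows
#' from the single config seed. Results are written as tidy CSV/JSON files
#' to `config$output_dir` and returned invisibly.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list with the fitted objects and summary
#'   tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  dat <- run_stage("data", {
    if (!is.null(config$simulate)) {
      simargs <- config$simulate
      n_nests <- simargs$n_nests %||% 6
      simargs$n_nests <- NULL
      simargs$seed <- seed
      simargs$site_latitude <- simargs$site_latitude %||% config$site_latitude
      cfg <- do.call(sim_config, simargs)
      profiles <- default_nest_profiles(n_nests)
      series <- simulate_temperature_series(profiles, cfg)
      curve <- true_curve_spec()
      list(
        profiles = profiles,
        series = series,
        activity = simulate_activity(series, curve, profiles,
                                     response = "count", seed = seed + 1),
        swarm = simulate_activity(series, curve, profiles,
                                  response = "speed", seed = seed + 2),
        surveys = simulate_surveys(profiles, trend = c("flat", "linear",
                                                       "quadratic"),
                                   seed = seed + 3)
      )
    } else {
      list(
        activity = read_activity_csv(config$activity_path),
        series = read_logger_csv(config$logger_path),
        surveys = read_survey_csv(config$survey_path),
        swarm = NULL
      )
    }
  })

  curves <- run_stage("curves", {
    hurdle <- fit_hurdle(dat$activity, mode = "primary")
    forage_win <- performance_window(hurdle, dat$activity, "foraging",
                                     fraction = config$fraction,
                                     grid_step = config$grid_step)
    swarm_fit <- swarm_win <- NULL
    if (!is.null(dat$swarm)) {
      active <- dat$swarm[dat$swarm$swarm_speed > 0, ]
      swarm_fit <- fit_additive(active, "swarm_speed",
                                smooths = list(smooth_spec("surface_temp")),
                                random = random_effect("nest_id"))
      swarm_win <- performance_window(swarm_fit, dat$swarm, "swarm",
                                      fraction = config$fraction,
                                      grid_step = config$grid_step)
    }
    windows <- dplyr::bind_rows(forage_win, swarm_win)
    list(hurdle = hurdle, swarm_fit = swarm_fit, windows = windows)
  })

  changepoint <- NULL
  if (!is.null(dat$swarm)) {
    changepoint <- run_stage("changepoint", {
      fit_emergence_changepoint(
        dat$swarm,
        iterations = config$mcmc$iterations %||% 1000,
        warmup = config$mcmc$warmup %||% 500,
        chains = config$mcmc$chains %||% 2,
        seed = seed + 4
      )
    })
  }

  budgets <- run_stage("budget", {
    w <- curves$windows[curves$windows$activity == "foraging", ]
    emergence <- available_hours(dat$series, w$emergence_lo, w$emergence_hi,
                                 config$site_latitude,
                                 coverage_threshold = config$coverage_threshold)
    optimal <- available_hours(dat$series, w$optimal_lo, w$optimal_hi,
                               config$site_latitude,
                               coverage_threshold = config$coverage_threshold)
    list(
      emergence = emergence,
      optimal = optimal,
      seasonal = seasonal_hours_summary(emergence)
    )
  })

  variance <- run_stage("variance", {
    daily <- summarize_daily(dat$series, config$site_latitude,
                             config$coverage_threshold)
    daily_ok <- daily[daily$complete, ]
    sets <- list(
      daily_min = fit_nested_models(daily_ok, "daytime_min"),
      daily_range = fit_nested_models(daily_ok, "daytime_range")
    )
    rlrt <- purrr::imap_dfr(sets, function(s, nm) {
      if (length(s$fits) < 2) return(tibble::tibble())
      r1 <- rlrt_simulation(s$fits$no_re, s$fits$intercept,
                            n_sim = config$n_sim_rlrt, seed = seed + 5)
      r2 <- rlrt_simulation(s$fits$intercept, s$fits$intercept_slope,
                            n_sim = config$n_sim_rlrt, seed = seed + 6)
      dplyr::bind_rows(
        dplyr::mutate(tidy(r1), response = nm,
                      comparison = "intercept vs none", .before = 1),
        dplyr::mutate(tidy(r2), response = nm,
                      comparison = "slope vs intercept", .before = 1)
      )
    })
    table <- purrr::imap_dfr(sets, function(s, nm) {
      dplyr::mutate(s$table, response = nm, .before = 1)
    })
    list(sets = sets, table = table, rlrt = rlrt, daily = daily)
  })

  colony <- run_stage("colony", {
    effort <- standardize_effort(dat$surveys)
    nests <- dplyr::inner_join(effort, budgets$seasonal, by = "nest_id")
    comp <- if (nrow(nests) >= 3) compensation_test(nests) else NULL
    growth <- fit_growth_models(dat$surveys)
    list(effort = effort, compensation = comp, growth = growth)
  })

  run_stage("write", {
    out <- config$output_dir
    readr::write_csv(curves$windows, file.path(out, "windows.csv"))
    readr::write_csv(predict(curves$hurdle), file.path(out, "curve_foraging.csv"))
    readr::write_csv(budgets$emergence, file.path(out, "budget_emergence.csv"))
    readr::write_csv(budgets$optimal, file.path(out, "budget_optimal.csv"))
    readr::write_csv(variance$table, file.path(out, "variance_models.csv"))
    if (nrow(variance$rlrt) > 0) {
      readr::write_csv(variance$rlrt, file.path(out, "rlrt.csv"))
    }
    readr::write_csv(colony$effort, file.path(out, "effort.csv"))
    if (!is.null(colony$compensation)) {
      readr::write_csv(colony$compensation, file.path(out, "compensation.csv"))
    }
    readr::write_csv(colony$growth, file.path(out, "growth_models.csv"))
    if (!is.null(changepoint)) {
      readr::write_csv(tidy(changepoint), file.path(out, "changepoint.csv"))
    }
    jsonlite::write_json(
      list(
        windows = curves$windows,
        curve_summaries = glance(curves$hurdle)
      ),
      file.path(out, "curves.json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA
    )
    jsonlite::write_json(
      list(seed = seed,
           r_version = as.character(getRversion()),
           package_version = as.character(utils::packageVersion("nestherm")),
           timestamp_utc = format(Sys.time(), tz = "UTC")),
      file.path(out, "run_log.json"), auto_unbox = TRUE
    )
  })

  invisible(list(data = dat, curves = curves, changepoint = changepoint,
                 budgets = budgets, variance = variance, colony = colony,
                 output_dir = config$output_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lenient ISO-8601 parser: per-row NA instead of an error on mixed formats
parse_iso8601 <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}
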