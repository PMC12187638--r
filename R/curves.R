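#' Fit a hurdle thermal performance model for foraging activity
#'
#' Two-part model of hourly worker counts: a logistic additive model of
#' worker presence on the trail (count > 0) fitted to all observations, and a
#' Poisson additive model of the number of workers fitted to the strictly
#' positive counts. Both parts carry a temperature smooth (k = 5 cubic
#' regression spline) and a nest-ID random intercept. The combined curve,
#' presence probability times conditional mean, is the activity measure used
#' for peak and window extraction.
#'
#' The `"primary"` mode uses surface temperature as the only covariate of
#' interest; `"adjusted"` additionally includes a parametric nest-size term
#' and a time-of-day smooth, with predictions benchmarked to the median nest
#' size and noon.
#'
#' The conditional count part is fitted as plain (untruncated) Poisson, an
#' approximation to the zero-truncated likelihood for the positive counts;
#' `truncated = TRUE` switches on a zero-truncation correction of the
#' conditional mean when combining the parts.
#'
#' @param obs activity observations: columns `nest_id`, `surface_temp`,
#'   `worker_count`, and for adjusted mode `nest_size`, `time_of_day`.
#' @param mode `"primary"` or `"adjusted"`.
#' @param k temperature-smooth basis dimension (default 5).
#' @param truncated apply the zero-truncation correction to the conditional
#'   mean (default `FALSE`).
#' @return an object of class `hurdle_curve` with components `presence_fit`
#'   and `count_fit` (both [fit_additive()] objects), the `mode`, the
#'   benchmark covariates, and the observed temperature range.
#' @export
fit_hurdle <- function(obs, mode = c("primary", "adjusted"), k = 5,
                       truncated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(obs))
  need <- c("nest_id", "surface_temp", "worker_count")
  if (mode == "adjusted") need <- c(need, "nest_size", "time_of_day")
  missing <- setdiff(need, names(obs))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  obs <- obs[!is.na(obs$worker_count) & !is.na(obs$surface_temp), ]
  if (nrow(obs) < 30) {
    stop("need at least 30 worker-count observations", call. = FALSE)
  }
  obs$present <- as.integer(obs$worker_count > 0)
  if (all(obs$present == 1) || all(obs$present == 0)) {
    stop("hurdle model needs both zero and positive counts", call. = FALSE)
  }
  smooths <- list(smooth_spec("surface_temp", k = k))
  linear <- NULL
  if (mode == "adjusted") {
    smooths <- c(smooths, list(smooth_spec("time_of_day", k = k)))
    linear <- "nest_size"
  }
  re <- random_effect("nest_id")
  presence_fit <- fit_additive(obs, "present", smooths = smooths,
                               linear_terms = linear, random = re,
                               family = "binomial")
  pos <- obs[obs$present == 1, , drop = FALSE]
  count_fit <- fit_additive(pos, "worker_count", smooths = smooths,
                            linear_terms = linear, random = re,
                            family = "poisson")
  benchmark <- NULL
  if (mode == "adjusted") {
    benchmark <- list(nest_size = stats::median(obs$nest_size, na.rm = TRUE),
                      time_of_day = 12)
  }
  structure(
    list(
      presence_fit = presence_fit,
      count_fit = count_fit,
      mode = mode,
      truncated = truncated,
      benchmark = benchmark,
      temp_range = range(obs$surface_temp),
      n = nrow(obs)
    ),
    class = "hurdle_curve"
  )
}

# covariates for curve prediction at given temperatures
curve_newdata <- function(curve, temp) {
  nd <- data.frame(surface_temp = temp)
  if (!is.null(curve$benchmark)) {
    for (v in names(curve$benchmark)) nd[[v]] <- curve$benchmark[[v]]
  }
  nd
}

#' Predict hurdle-curve components over temperature
#'
#' @param object a `hurdle_curve`.
#' @param temp temperatures (degrees C); default a 0.1-degree grid over the
#'   observed range.
#' @param ... unused.
#' @return a tibble with `surface_temp`, `presence` (probability),
#'   `conditional` (mean workers once present) and `combined`
#'   (presence x conditional, the expected activity).
#' @export
predict.hurdle_curve <- function(object, temp = NULL, ...) {
  if (is.null(temp)) {
    temp <- seq(object$temp_range[1], object$temp_range[2], by = 0.1)
  }
  nd <- curve_newdata(object, temp)
  p <- predict(object$presence_fit, nd)
  # the count part is trained on positive counts only; evaluating it across
  # the full observed range is intended (presence -> 0 dominates the tails)
  mu <- suppressWarnings(predict(object$count_fit, nd))
  cond <- if (isTRUE(object$truncated)) mu / (1 - exp(-mu)) else mu
  tibble::tibble(
    surface_temp = temp,
    presence = as.numeric(p),
    conditional = as.numeric(cond),
    combined = as.numeric(p) * as.numeric(cond)
  )
}

#' @export
print.hurdle_curve <- function(x, ...) {
  cat("Hurdle thermal performance curve (", x$mode, " mode)\n", sep = "")
  cat("  n =", x$n, "observations, temperature range",
      sprintf("%.1f-%.1f", x$temp_range[1], x$temp_range[2]), "C\n")
  cat("  presence deviance explained =",
      sprintf("%.1f%%", 100 * x$presence_fit$deviance_explained), "\n")
  cat("  count deviance explained =",
      sprintf("%.1f%%", 100 * x$count_fit$deviance_explained), "\n")
  invisible(x)
}

#' @export
tidy.hurdle_curve <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$presence_fit), part = "presence", .before = 1),
    dplyr::mutate(tidy(x$count_fit), part = "count", .before = 1)
  )
}

#' @export
glance.hurdle_curve <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$presence_fit), part = "presence", .before = 1),
    dplyr::mutate(glance(x$count_fit), part = "count", .before = 1)
  )
}

# evaluate the scalar activity curve used for peak/window extraction
curve_values <- function(curve, temp) {
  if (inherits(curve, "hurdle_curve")) {
    predict(curve, temp)$combined
  } else if (inherits(curve, "additive_fit")) {
    v <- curve$design_description$smooths[[1]]$variable
    nd <- stats::setNames(data.frame(temp), v)
    as.numeric(predict(curve, nd))
  } else {
    stop("`curve` must be a hurdle_curve or additive_fit", call. = FALSE)
  }
}

curve_temp_range <- function(curve) {
  if (inherits(curve, "hurdle_curve")) return(curve$temp_range)
  v <- curve$design_description$smooths[[1]]$variable
  curve$train_range[[v]]
}

#' Locate the temperature of peak activity
#'
#' Evaluates the fitted activity curve (the combined hurdle expectation, or
#' the mean response of a Gaussian additive fit) on a regular grid over the
#' observed temperature range and returns the argmax. Ties are broken toward
#' the lower temperature; a peak at either end of the observed range is
#' flagged as a boundary peak.
#'
#' @param curve a `hurdle_curve` or `additive_fit`.
#' @param grid_step grid resolution in degrees C (default 0.1).
#' @return a one-row tibble with `peak_temp`, `peak_value`, `boundary`.
#' @export
find_peak <- function(curve, grid_step = 0.1) {
  r <- curve_temp_range(curve)
  grid <- seq(r[1], r[2], by = grid_step)
  v <- curve_values(curve, grid)
  if (any(!is.finite(v))) stop("non-finite curve predictions", call. = FALSE)
  i <- which.max(v)
  tibble::tibble(
    peak_temp = grid[i],
    peak_value = v[i],
    boundary = i == 1L || i == length(grid)
  )
}

#' Optimal temperature window at a fraction of maximum activity
#'
#' The maximal contiguous temperature interval containing the peak over which
#' predicted activity stays at or above `fraction` of the peak value (the
#' 90% window by default). Not defined for boundary peaks.
#'
#' @param curve a `hurdle_curve` or `additive_fit`.
#' @param fraction fraction of maximum in `(0, 1]` (default 0.90).
#' @param grid_step grid resolution in degrees C.
#' @return a one-row tibble with `optimal_lo`, `optimal_hi`, `peak_temp`,
#'   `fraction`, `boundary`. For a boundary peak the window bounds are `NA`.
#' @export
optimal_window <- function(curve, fraction = 0.90, grid_step = 0.1) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  r <- curve_temp_range(curve)
  grid <- seq(r[1], r[2], by = grid_step)
  v <- curve_values(curve, grid)
  i <- which.max(v)
  boundary <- i == 1L || i == length(grid)
  if (boundary) {
    warning("boundary peak: optimal window undefined", call. = FALSE)
    return(tibble::tibble(optimal_lo = NA_real_, optimal_hi = NA_real_,
                          peak_temp = grid[i], fraction = fraction,
                          boundary = TRUE))
  }
  thr <- fraction * v[i]
  lo <- i
  while (lo > 1 && v[lo - 1] >= thr) lo <- lo - 1
  hi <- i
  while (hi < length(v) && v[hi + 1] >= thr) hi <- hi + 1
  tibble::tibble(
    optimal_lo = grid[lo], optimal_hi = grid[hi],
    peak_temp = grid[i], fraction = fraction, boundary = FALSE
  )
}

#' Emergence temperature window
#'
#' The temperature interval over which workers are active outside the nest at
#' all. The observed-range method returns the minimum and maximum surface
#' temperature across active observations (count > 0 or speed > 0); the
#' model-based method returns the temperatures at which the fitted presence
#' probability crosses 0.5.
#'
#' @param obs activity observations with `surface_temp` and either
#'   `worker_count` or `swarm_speed`.
#' @param method `"observed-range"` or `"model-based"`.
#' @param curve a fitted `hurdle_curve`, required for the model-based method.
#' @param grid_step grid resolution for the model-based crossing search.
#' @return a one-row tibble with `emergence_lo`, `emergence_hi`, `method`.
#' @export
emergence_window <- function(obs, method = c("observed-range", "model-based"),
                             curve = NULL, grid_step = 0.1) {
  method <- match.arg(method)
  if (method == "observed-range") {
    act <- rep(FALSE, nrow(obs))
    if ("worker_count" %in% names(obs)) {
      act <- act | (!is.na(obs$worker_count) & obs$worker_count > 0)
    }
    if ("swarm_speed" %in% names(obs)) {
      act <- act | (!is.na(obs$swarm_speed) & obs$swarm_speed > 0)
    }
    temps <- obs$surface_temp[act]
    if (length(temps) == 0) stop("no active observations", call. = FALSE)
    tibble::tibble(emergence_lo = min(temps), emergence_hi = max(temps),
                   method = method)
  } else {
    if (is.null(curve)) {
      stop("`curve` is required for the model-based method", call. = FALSE)
    }
    r <- curve$temp_range
    grid <- seq(r[1], r[2], by = grid_step)
    p <- predict(curve, grid)$presence
    above <- which(p >= 0.5)
    if (length(above) == 0) stop("presence never reaches 0.5", call. = FALSE)
    tibble::tibble(emergence_lo = grid[min(above)],
                   emergence_hi = grid[max(above)], method = method)
  }
}

#' Liberal and conservative upper-threshold estimates
#'
#' When upper-tail data are too sparse for model-based estimation, the upper
#' temperature threshold is bracketed empirically: the liberal estimate is
#' the maximum temperature at which workers were still observed to emerge,
#' and the conservative estimate is the median temperature of the
#' non-emergence observations.
#'
#' @param obs observations with `surface_temp` and a logical `emerged` flag.
#' @return a one-row tibble with `liberal`, `conservative`,
#'   `n_emerged`, `n_non_emerged`, and `consistent` (`TRUE` when
#'   liberal < conservative, i.e. every emergence was cooler than the typical
#'   non-emergence).
#' @export
upper_threshold_estimates <- function(obs) {
  stopifnot(all(c("surface_temp", "emerged") %in% names(obs)))
  em <- obs$surface_temp[obs$emerged]
  non <- obs$surface_temp[!obs$emerged]
  liberal <- if (length(em)) max(em) else NA_real_
  conservative <- if (length(non)) stats::median(non) else NA_real_
  if (length(em) == 0) message("no emergence observations: liberal estimate unavailable")
  if (length(non) == 0) message("no non-emergence observations: conservative estimate unavailable")
  tibble::tibble(
    liberal = liberal, conservative = conservative,
    n_emerged = length(em), n_non_emerged = length(non),
    consistent = !is.na(liberal) && !is.na(conservative) &&
      liberal < conservative
  )
}

#' Assemble a performance window summary
#'
#' Combines the peak, the optimal (fraction-of-maximum) window and the
#' emergence window for one activity type into a single record, enforcing the
#' nesting `emergence_lo <= optimal_lo <= peak <= optimal_hi <= emergence_hi`.
#'
#' @param curve a fitted `hurdle_curve` or `additive_fit`.
#' @param obs the observations the curve was fitted to (for the emergence
#'   window).
#' @param activity label, e.g. `"foraging"` or `"swarm"`.
#' @param fraction optimal-window fraction (default 0.90).
#' @param grid_step grid resolution in degrees C.
#' @param emergence_method passed to [emergence_window()].
#' @return a one-row tibble with the activity label, peak, optimal and
#'   emergence bounds, and the methods used.
#' @export
performance_window <- function(curve, obs, activity = "foraging",
                               fraction = 0.90, grid_step = 0.1,
                               emergence_method = "observed-range") {
  pk <- find_peak(curve, grid_step)
  ow <- optimal_window(curve, fraction, grid_step)
  ew <- emergence_window(obs, emergence_method,
                         curve = if (inherits(curve, "hurdle_curve")) curve,
                         grid_step = grid_step)
  out <- tibble::tibble(
    activity = activity,
    peak_temp = pk$peak_temp,
    optimal_lo = ow$optimal_lo, optimal_hi = ow$optimal_hi,
    fraction = fraction,
    emergence_lo = ew$emergence_lo, emergence_hi = ew$emergence_hi,
    method_emergence = ew$method,
    boundary_peak = pk$boundary
  )
  if (!pk$boundary &&
      (out$emergence_lo > out$optimal_lo + grid_step ||
       out$optimal_hi > out$emergence_hi + grid_step)) {
    warning("optimal window extends beyond the emergence window; ",
            "emergence bounds may be undersampled", call. = FALSE)
  }
  out
}
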