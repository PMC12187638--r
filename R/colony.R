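#' Size-independent foraging-effort standardization
#'
#' Estimates each nest's foraging effort independent of its size. The yearly
#' total of foraging and tree trails is log10-transformed and modelled as a
#' function of nest size with a random intercept and slope per nest ID
#' (`lme4::lmer`). Each nest's coefficient — its prediction at the
#' population-mean size — is extracted and back-transformed (`10^x`) to give
#' a standardized trail count averaged over the monitored years.
#'
#' @param surveys survey records: `nest_id`, `year`, `entrance_holes`,
#'   `n_foraging_trails`, `n_tree_trails` (and optionally
#'   `n_connection_trails`).
#' @param include_connection include connection trails in the total
#'   (default `FALSE`: foraging effort is indexed by foraging and tree
#'   trails).
#' @param zero_policy nest-years with zero total trails cannot enter the
#'   log10 response: `"drop"` (default) excludes them with a warning,
#'   `"add1"` uses `log10(x + 1)`.
#' @return a tibble with `nest_id`, `standardized_trails`, `mean_size`,
#'   `n_years`; the fitted `lmerMod` is attached as attribute `model`.
#' @export
standardize_effort <- function(surveys,
                               include_connection = FALSE,
                               zero_policy = c("drop", "add1")) {
  zero_policy <- match.arg(zero_policy)
  need <- c("nest_id", "year", "entrance_holes", "n_foraging_trails",
            "n_tree_trails")
  stopifnot(all(need %in% names(surveys)))
  n_nests <- length(unique(surveys$nest_id))
  if (n_nests < 3) stop("need at least 3 nests", call. = FALSE)
  if (n_nests < 10) {
    warning("fewer than 10 nests: random-slope estimates may be unstable",
            call. = FALSE)
  }
  total <- surveys$n_foraging_trails + surveys$n_tree_trails
  if (include_connection && "n_connection_trails" %in% names(surveys)) {
    total <- total + surveys$n_connection_trails
  }
  d <- tibble::tibble(
    nest_id = factor(surveys$nest_id),
    size = surveys$entrance_holes,
    total = total
  )
  if (zero_policy == "drop") {
    nzero <- sum(d$total == 0)
    if (nzero > 0) {
      warning(nzero, " zero-trail nest-years excluded from the log10 response",
              call. = FALSE)
      d <- d[d$total > 0, , drop = FALSE]
    }
    d$log_trails <- log10(d$total)
  } else {
    d$log_trails <- log10(d$total + 1)
  }
  d$size_c <- d$size - mean(d$size)
  model <- suppressMessages(
    lme4::lmer(log_trails ~ size_c + (1 + size_c | nest_id), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  )
  # per-nest intercepts are predictions at the population-mean size
  cf <- stats::coef(model)$nest_id
  per_nest <- tibble::tibble(
    nest_id = rownames(cf),
    standardized_trails = 10^cf[["(Intercept)"]]
  )
  sizes <- surveys |>
    dplyr::group_by(nest_id = as.character(.data$nest_id)) |>
    dplyr::summarise(mean_size = mean(.data$entrance_holes),
                     n_years = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(per_nest, sizes, by = "nest_id")
  attr(out, "model") <- model
  out
}

#' Behavioural compensation test
#'
#' Asks whether colonies offset thermal restrictions on foraging time by
#' increasing foraging effort. For each season (summer apex and winter base
#' of the daily-hours trend), ordinary least-squares trends of (a) mean nest
#' size and (b) size-independent standardized trail count against the
#' available foraging hours are reported. Under compensation, size should be
#' unrelated to hours while effort should *increase* as hours decrease
#' (negative slope); a positive size trend with no effort increase indicates
#' a failure to compensate. Signs and magnitudes are reported without a
#' decision rule.
#'
#' @param nests a tibble with one row per nest: `nest_id`, `mean_size`,
#'   `standardized_trails`, `hours_summer`, `hours_winter` (join of
#'   [standardize_effort()] and [seasonal_hours_summary()]).
#' @return a tibble with one row per response-season pair: `response`,
#'   `season`, `slope`, `std_error`, `t_value`, `p_value`, `n`, `degenerate`.
#' @export
compensation_test <- function(nests) {
  need <- c("nest_id", "mean_size", "standardized_trails",
            "hours_summer", "hours_winter")
  stopifnot(all(need %in% names(nests)))
  if (nrow(nests) < 3) stop("fewer than 3 nests with both effort and hours",
                            call. = FALSE)
  grid <- tidyr::expand_grid(
    response = c("mean_size", "standardized_trails"),
    season = c("summer", "winter")
  )
  purrr::pmap_dfr(grid, function(response, season) {
    x <- nests[[paste0("hours_", season)]]
    y <- nests[[response]]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(response = response, season = season,
                            slope = NA_real_, std_error = NA_real_,
                            t_value = NA_real_, p_value = NA_real_,
                            n = length(x), degenerate = TRUE))
    }
    fit <- stats::lm(y ~ x)
    cf <- summary(fit)$coefficients
    tibble::tibble(
      response = response, season = season,
      slope = cf["x", 1], std_error = cf["x", 2],
      t_value = cf["x", 3], p_value = cf["x", 4],
      n = length(x), degenerate = FALSE
    )
  })
}

# AICc with the small-sample correction; k counts all estimated parameters
# (regression coefficients plus the residual variance)
aicc <- function(fit) {
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  if (n - k - 1 <= 0) return(NA_real_)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Longitudinal nest-growth model selection
#'
#' Compares three models of annual nest size (entrance holes) for each nest:
#' intercept-only (no annual change), linear change, and quadratic change,
#' with years centred at the first monitored year. Models are ranked by AICc
#' (`AIC + 2k(k+1)/(n-k-1)`); any model within two AICc units of the best is
#' flagged as well supported, and t-values for the year and year-squared
#' terms give the direction and magnitude of change. Models whose AICc
#' correction is undefined (`n - k - 1 <= 0`) are omitted with a notice.
#'
#' @param sizes per-year sizes: columns `year`, `entrance_holes`, and
#'   optionally `nest_id` (multiple nests are fitted independently).
#' @param drop_years years to exclude before fitting (e.g. re-run a series
#'   without its first survey year).
#' @return a tibble with one row per nest-model: `nest_id`, `model`,
#'   `n_years`, `aicc`, `delta_aicc`, `t_years`, `t_years2`, `supported`.
#' @export
fit_growth_models <- function(sizes, drop_years = NULL) {
  stopifnot(all(c("year", "entrance_holes") %in% names(sizes)))
  if (!"nest_id" %in% names(sizes)) sizes$nest_id <- "nest"
  if (!is.null(drop_years)) sizes <- sizes[!sizes$year %in% drop_years, ]
  purrr::map_dfr(split(sizes, sizes$nest_id), function(d) {
    d <- d[order(d$year), ]
    d$yr <- d$year - min(d$year)
    n <- nrow(d)
    if (n < 3) stop("need at least 3 years per nest", call. = FALSE)
    if (stats::sd(d$entrance_holes) == 0) {
      # constant series: likelihoods are unbounded, the no-change model is
      # selected by construction
      message("constant size series: intercept model selected")
      return(tibble::tibble(
        nest_id = d$nest_id[1], model = "intercept", n_years = n,
        aicc = NA_real_, t_years = NA_real_, t_years2 = NA_real_,
        delta_aicc = 0, supported = TRUE
      ))
    }
    fits <- list(
      intercept = stats::lm(entrance_holes ~ 1, data = d),
      linear = stats::lm(entrance_holes ~ yr, data = d),
      quadratic = stats::lm(entrance_holes ~ yr + I(yr^2), data = d)
    )
    rows <- purrr::imap_dfr(fits, function(f, nm) {
      a <- aicc(f)
      cf <- summary(f)$coefficients
      tibble::tibble(
        nest_id = d$nest_id[1],
        model = nm,
        n_years = n,
        aicc = a,
        t_years = if (nm != "intercept" && "yr" %in% rownames(cf)) {
          cf["yr", "t value"]
        } else NA_real_,
        t_years2 = if (nm == "quadratic" && "I(yr^2)" %in% rownames(cf)) {
          cf["I(yr^2)", "t value"]
        } else NA_real_
      )
    })
    dropped <- rows$model[is.na(rows$aicc)]
    if (length(dropped) > 0) {
      message("AICc undefined for ", paste(dropped, collapse = ", "),
              " (n - k - 1 <= 0): model omitted")
      rows <- rows[!is.na(rows$aicc), ]
    }
    rows$delta_aicc <- rows$aicc - min(rows$aicc)
    rows$supported <- rows$delta_aicc <= 2
    rows
  })
}
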