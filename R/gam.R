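#' Smooth-term specification
#'
#' Describes one penalized spline term: a cubic regression spline (or its
#' cyclic variant) with `k` basis functions, knots at quantiles of the data,
#' a second-order (curvature) penalty, and a sum-to-zero identifiability
#' constraint (the model intercept carries the mean).
#'
#' @param variable name of the covariate.
#' @param k basis dimension, `3 <= k <= 20` (default 5, matching a
#'   low-rank curve for hourly field counts).
#' @param basis `"cr"` (cubic regression spline) or `"cc"` (cyclic, for
#'   day-of-year seasonality).
#' @return a list of class `smooth_spec`.
#' @export
smooth_spec <- function(variable, k = 5, basis = c("cr", "cc")) {
  basis <- match.arg(basis)
  if (k < 3 || k > 20) stop("`k` must lie in [3, 20]", call. = FALSE)
  structure(list(variable = variable, k = as.integer(k), basis = basis),
            class = "smooth_spec")
}

#' Random-effect specification
#'
#' A factor random effect (typically nest ID), either intercept-only or
#' intercept plus a random slope in a named covariate. Represented internally
#' as ridge-penalized indicator blocks with separate variance parameters,
#' estimated by REML alongside the smooths.
#'
#' @param grouping name of the grouping factor column.
#' @param structure `"intercept"` or `"intercept+slope"`.
#' @param slope_variable covariate name; required iff
#'   `structure == "intercept+slope"`.
#' @return a list of class `random_effect`.
#' @export
random_effect <- function(grouping, structure = c("intercept", "intercept+slope"),
                          slope_variable = NULL) {
  structure <- match.arg(structure)
  if (structure == "intercept+slope" && is.null(slope_variable)) {
    stop("`slope_variable` is required for intercept+slope", call. = FALSE)
  }
  if (structure == "intercept" && !is.null(slope_variable)) {
    stop("`slope_variable` only applies to intercept+slope", call. = FALSE)
  }
  structure(list(grouping = grouping, structure = structure,
                 slope_variable = slope_variable),
            class = "random_effect")
}

#' Build a spline basis and penalty matrix
#'
#' Constructs the centred (sum-to-zero) spline basis and its positive
#' semidefinite curvature penalty for a covariate, with knots at quantiles of
#' the data. After the identifiability constraint is absorbed the basis has
#' `k - 1` columns; together with the model intercept this spans the usual
#' k-dimensional spline space.
#'
#' @param x numeric covariate values (at least `k` distinct values).
#' @param spec a [smooth_spec()].
#' @return a list with `basis` (n x (k-1) matrix), `penalty`
#'   ((k-1) x (k-1) PSD matrix), `knots`, and the `spec`; class `spline_basis`.
#' @export
build_basis <- function(x, spec) {
  stopifnot(inherits(spec, "smooth_spec"))
  if (length(unique(x)) < spec$k) {
    stop("need at least k distinct covariate values", call. = FALSE)
  }
  df <- stats::setNames(data.frame(x = x), spec$variable)
  sm <- mgcv::smoothCon(
    eval(parse(text = sprintf("mgcv::s(%s, k = %d, bs = '%s')",
                              spec$variable, spec$k, spec$basis))),
    data = df, absorb.cons = TRUE, scale.penalty = FALSE
  )[[1]]
  structure(
    list(basis = sm$X, penalty = sm$S[[1]], knots = sm$xp, spec = spec,
         smooth = sm),
    class = "spline_basis"
  )
}

# build the mgcv formula for fit_additive
build_gam_formula <- function(response, smooths, linear_terms, random) {
  terms <- character(0)
  if (!is.null(linear_terms)) terms <- c(terms, linear_terms)
  for (s in smooths) {
    terms <- c(terms, sprintf("s(%s, k = %d, bs = '%s')",
                              s$variable, s$k, s$basis))
  }
  if (!is.null(random)) {
    terms <- c(terms, sprintf("s(%s, bs = 're')", random$grouping))
    if (random$structure == "intercept+slope") {
      terms <- c(terms, sprintf("s(%s, %s, bs = 're')",
                                random$slope_variable, random$grouping))
    }
  }
  if (length(terms) == 0) terms <- "1"
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

#' Fit a penalized-spline additive model
#'
#' Penalized additive model with optional factor random effects, fitted by
#' penalized IRLS with smoothing parameters chosen by REML (via `mgcv::gam`).
#' Gaussian, binomial and Poisson families are supported. Random effects
#' enter as ridge-penalized indicator blocks whose variance parameters are
#' estimated with the smoothing parameters.
#'
#' The returned object carries the effective degrees of freedom (EDF) per
#' term, total EDF, log-likelihood, deviance explained, AIC, and an EDF-based
#' BIC (`-2*loglik + total_edf*log(n)`), which is the dimension measure used
#' to rank penalized mixed-spline models.
#'
#' @param data a data frame.
#' @param response name of the response column.
#' @param smooths list of [smooth_spec()] terms.
#' @param linear_terms character vector of parametric term names (optional).
#' @param random a [random_effect()] (optional).
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param sp fixed smoothing parameters (optional; passed to `mgcv::gam`,
#'   `-1` entries are estimated).
#' @param knots optional named list of knot positions (e.g. cyclic endpoints).
#' @param subset optional logical vector of rows to use.
#' @return an object of class `additive_fit`.
#' @examples
#' d <- data.frame(x = seq(0, 1, length.out = 50))
#' d$y <- sin(2 * pi * d$x) + rnorm(50, 0, 0.2)
#' f <- fit_additive(d, "y", smooths = list(smooth_spec("x", k = 8)))
#' glance(f)
#' @export
fit_additive <- function(data, response,
                         smooths = list(),
                         linear_terms = NULL,
                         random = NULL,
                         family = c("gaussian", "binomial", "poisson"),
                         sp = NULL, knots = NULL, subset = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data))
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  if (nrow(data) < 10) stop("need at least 10 observations", call. = FALSE)
  if (!response %in% names(data)) {
    stop("response column not found: ", response, call. = FALSE)
  }
  if (!is.null(random)) {
    data[[random$grouping]] <- droplevels(factor(data[[random$grouping]]))
  }
  form <- build_gam_formula(response, smooths, linear_terms, random)
  fam <- switch(family,
                gaussian = stats::gaussian(),
                binomial = stats::binomial(),
                poisson = stats::poisson())
  warn <- character(0)
  g <- withCallingHandlers(
    mgcv::gam(form, data = data, family = fam, method = "REML",
              sp = sp, knots = knots),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!g$converged) {
    warn <- c(warn, "penalized IRLS did not converge")
  }
  n <- length(g$y)
  edf_term <- purrr::map_dbl(g$smooth, function(sm) {
    sum(g$edf[sm$first.para:sm$last.para])
  })
  names(edf_term) <- purrr::map_chr(g$smooth, "label")
  total_edf <- sum(g$edf)
  ll <- as.numeric(stats::logLik(g))
  dev_expl <- (g$null.deviance - g$deviance) / g$null.deviance
  structure(
    list(
      gam = g,
      family = family,
      response = response,
      coefficients = stats::coef(g),
      smoothing_params = if (length(g$sp)) g$sp else g$full.sp,
      edf_per_term = edf_term,
      total_edf = total_edf,
      log_likelihood = ll,
      deviance_explained = dev_expl,
      aic = stats::AIC(g),
      bic = -2 * ll + total_edf * log(n),
      n = n,
      train_range = purrr::map(
        stats::setNames(nm = purrr::map_chr(smooths, "variable")),
        function(v) range(data[[v]], na.rm = TRUE)
      ),
      design_description = list(smooths = smooths,
                                linear_terms = linear_terms,
                                random = random),
      warnings = warn
    ),
    class = "additive_fit"
  )
}

#' Predict from an additive fit
#'
#' Deterministic predictions on the inverse-link (response) scale, with
#' optional pointwise standard errors. Random-effect terms are excluded by
#' default so predictions describe a population-typical unit. Requests more
#' than 10% beyond the training range of any smooth covariate are flagged
#' with a warning and an `extrapolated` attribute.
#'
#' @param object an `additive_fit`.
#' @param newdata data frame of covariate values.
#' @param se return standard errors as well (link-scale SEs mapped through
#'   the inverse link at the mean)?
#' @param include_random include the random-effect contributions?
#' @param ... unused.
#' @return a numeric vector of mean responses, or a tibble with `fit` and
#'   `se` when `se = TRUE`.
#' @export
predict.additive_fit <- function(object, newdata, se = FALSE,
                                 include_random = FALSE, ...) {
  g <- object$gam
  needed <- setdiff(all.vars(stats::formula(g))[-1], object$response)
  if (!include_random && !is.null(object$design_description$random)) {
    re <- object$design_description$random
    # supply a placeholder level; the term itself is excluded below
    lev <- levels(g$model[[re$grouping]])[1]
    if (!re$grouping %in% names(newdata)) newdata[[re$grouping]] <- lev
  }
  missing <- setdiff(needed, names(newdata))
  if (length(missing) > 0) {
    stop("missing prediction variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extrapolated <- FALSE
  for (v in names(object$train_range)) {
    r <- object$train_range[[v]]
    pad <- 0.1 * diff(r)
    if (v %in% names(newdata) &&
        any(newdata[[v]] < r[1] - pad | newdata[[v]] > r[2] + pad)) {
      extrapolated <- TRUE
    }
  }
  if (extrapolated) {
    warning("prediction grid extends > 10% beyond the training range",
            call. = FALSE)
  }
  exclude <- NULL
  if (!include_random && !is.null(object$design_description$random)) {
    re_labels <- purrr::map_chr(g$smooth, "label")
    re_dims <- purrr::map_chr(g$smooth, function(sm) class(sm)[1])
    exclude <- re_labels[re_dims == "random.effect"]
  }
  pr <- mgcv::predict.gam(g, newdata = newdata, type = "link",
                          se.fit = se, exclude = exclude,
                          newdata.guaranteed = TRUE)
  inv <- g$family$linkinv
  if (se) {
    out <- tibble::tibble(fit = inv(pr$fit),
                          se = as.numeric(pr$se.fit) *
                            abs(g$family$mu.eta(pr$fit)))
    attr(out, "extrapolated") <- extrapolated
    out
  } else {
    out <- inv(as.numeric(pr))
    attr(out, "extrapolated") <- extrapolated
    out
  }
}

#' @export
print.additive_fit <- function(x, ...) {
  cat("Penalized additive model (", x$family, ")\n", sep = "")
  cat("  n =", x$n, " total EDF =", round(x$total_edf, 2), "\n")
  cat("  deviance explained =", sprintf("%.1f%%", 100 * x$deviance_explained),
      "\n")
  cat("  AIC =", round(x$aic, 1), " BIC(EDF) =", round(x$bic, 1), "\n")
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Tidy an additive fit
#'
#' One row per model term: parametric coefficients with estimates and
#' standard errors, smooth and random-effect terms with their EDF and test
#' statistics.
#'
#' @param x an `additive_fit`.
#' @param ... unused.
#' @return a tibble with columns `term`, `type`, `estimate`, `std_error`,
#'   `edf`, `statistic`, `p_value`.
#' @export
tidy.additive_fit <- function(x, ...) {
  s <- summary(x$gam)
  par <- tibble::tibble(
    term = rownames(s$p.table),
    type = "parametric",
    estimate = s$p.table[, 1],
    std_error = s$p.table[, 2],
    edf = NA_real_,
    statistic = s$p.table[, 3],
    p_value = s$p.table[, 4]
  )
  if (!is.null(s$s.table) && nrow(s$s.table) > 0) {
    sm <- tibble::tibble(
      term = rownames(s$s.table),
      type = "smooth",
      estimate = NA_real_,
      std_error = NA_real_,
      edf = s$s.table[, "edf"],
      statistic = s$s.table[, 3],
      p_value = s$s.table[, 4]
    )
    par <- dplyr::bind_rows(par, sm)
  }
  par
}

#' Glance at an additive fit
#'
#' @param x an `additive_fit`.
#' @param ... unused.
#' @return a one-row tibble with `n`, `total_edf`, `log_likelihood`,
#'   `deviance_explained`, `aic`, `bic`.
#' @export
glance.additive_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    total_edf = x$total_edf,
    log_likelihood = x$log_likelihood,
    deviance_explained = x$deviance_explained,
    aic = x$aic,
    bic = x$bic
  )
}
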