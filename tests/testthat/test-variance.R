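range_model_set <- function(seed, amplitudes, months = 4, k = 8,
                            seasonal_amplitude = 6) {
  prof <- nest_profiles(paste0("N", seq_along(amplitudes)),
                        exposure_amplitude = amplitudes,
                        seasonal_amplitude = seasonal_amplitude)
  cfg <- sim_config(
    date_range = as.Date(c("2019-01-01",
                           sprintf("2019-%02d-28", months))),
    noise_sd = 1.5, seed = seed
  )
  ser <- simulate_temperature_series(prof, cfg)
  d <- summarize_daily(ser)
  fit_nested_models(d[d$complete, ], "daytime_range", k = k)
}

test_that("BIC prefers no random effect when nests are exchangeable", {
  picks <- vapply(1:15, function(s) {
    st <- range_model_set(s, amplitudes = rep(15, 6))
    st$table$model[which.min(st$table$bic)]
  }, character(1))
  expect_gte(mean(picks == "no_re"), 0.8)
})

test_that("BIC prefers the random intercept when nests differ in warming", {
  picks <- vapply(1:15, function(s) {
    st <- range_model_set(s, amplitudes = seq(10, 25, length.out = 6))
    st$table$model[which.min(st$table$bic)]
  }, character(1))
  expect_gte(mean(picks == "intercept"), 0.8)
})

test_that("a single nest skips the random-effect models with a notice", {
  prof <- nest_profiles("N1", exposure_amplitude = 15)
  cfg <- sim_config(date_range = as.Date(c("2019-01-01", "2019-03-31")),
                    noise_sd = 1.5, seed = 4)
  d <- summarize_daily(simulate_temperature_series(prof, cfg))
  expect_message(st <- fit_nested_models(d, "daytime_range"), "single nest")
  expect_named(st$fits, "no_re")
  expect_error(fit_nested_models(d[1:10, ], "daytime_range"), "30 days")
})

test_that("the RLRT statistic is non-negative and the null mass sits at zero", {
  st <- range_model_set(21, amplitudes = rep(15, 6))
  r <- rlrt_simulation(st$fits$no_re, st$fits$intercept, n_sim = 499,
                       seed = 5)
  expect_gte(r$statistic, 0)
  expect_true(all(r$sim_stats >= 0))
  # boundary mixture: roughly half of the null statistics are exactly zero
  expect_gte(r$prop_zero, 0.3)
  expect_lte(r$prop_zero, 0.7)
  expect_gte(r$p_value, 0)
  expect_lte(r$p_value, 1)
})

test_that("a zero observed statistic yields a p-value near one", {
  # search a few seeds for a replicate whose observed statistic is zero
  found <- FALSE
  for (s in 1:12) {
    st <- range_model_set(s + 40, amplitudes = rep(15, 6), months = 3)
    r <- rlrt_simulation(st$fits$no_re, st$fits$intercept, n_sim = 99,
                         seed = s)
    if (r$statistic == 0) {
      expect_gt(r$p_value, 0.3)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("a large true variance component is detected decisively", {
  ps <- vapply(1:10, function(s) {
    st <- range_model_set(s + 60, amplitudes = seq(8, 28, length.out = 6),
                          months = 3)
    rlrt_simulation(st$fits$no_re, st$fits$intercept, n_sim = 199,
                    seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.95)
})

test_that("the RLRT is not anticonservative on skewed daily-range responses", {
  # daily temperature ranges are right-skewed; the Gaussian parametric
  # bootstrap runs slightly conservative there, and must never inflate the
  # false-positive rate
  rejected <- vapply(1:100, function(s) {
    st <- range_model_set(s + 300, amplitudes = rep(15, 6), months = 4)
    rlrt_simulation(st$fits$no_re, st$fits$intercept, n_sim = 99,
                    seed = s + 4000)$p_value <= 0.05
  }, logical(1))
  expect_lte(mean(rejected), 0.08)
})

test_that("non-nested or mismatched model pairs are rejected", {
  st <- range_model_set(33, amplitudes = seq(10, 25, length.out = 4),
                        months = 3)
  expect_error(rlrt_simulation(st$fits$no_re, st$fits$intercept_slope),
               "exactly one random-effect block")
  expect_error(rlrt_simulation(st$fits$intercept, st$fits$no_re),
               "exactly one random-effect block")
  st2 <- range_model_set(34, amplitudes = seq(10, 25, length.out = 4),
                         months = 3)
  expect_error(rlrt_simulation(st$fits$no_re, st2$fits$intercept),
               "same response")
  expect_error(
    rlrt_simulation(st$fits$no_re, st$fits$intercept, n_sim = 0),
    "positive"
  )
})

test_that("BIC ordering is invariant to affine rescaling of the response", {
  st <- range_model_set(35, amplitudes = seq(10, 25, length.out = 6),
                        months = 3)
  prof <- nest_profiles(paste0("N", 1:6),
                        exposure_amplitude = seq(10, 25, length.out = 6),
                        seasonal_amplitude = 6)
  cfg <- sim_config(date_range = as.Date(c("2019-01-01", "2019-03-28")),
                    noise_sd = 1.5, seed = 35)
  d <- summarize_daily(simulate_temperature_series(prof, cfg))
  d <- d[d$complete, ]
  d$scaled <- 2 * d$daytime_range + 3
  st2 <- fit_nested_models(d, "scaled")
  expect_equal(st$table$delta_bic, st2$table$delta_bic, tolerance = 0.05)
})

test_that("the RLRT engine matches a dense restricted-likelihood evaluation", {
  # cross-check the profiled statistic against the O(n^2) reference formula
  st <- range_model_set(36, amplitudes = seq(12, 22, length.out = 4),
                        months = 3)
  null_fit <- st$fits$no_re
  alt_fit <- st$fits$intercept
  r <- rlrt_simulation(null_fit, alt_fit, n_sim = 5, seed = 9)
  dn <- nestherm:::decompose_design(null_fit)
  da <- nestherm:::decompose_design(alt_fit)
  y <- dn$y
  X <- dn$X
  C_spline <- dn$blocks[[1]]$C
  Z <- da$blocks[[2]]$C
  n <- length(y)
  p <- ncol(X)
  reml_dense <- function(lam_f, psi) {
    V <- diag(n) + lam_f * tcrossprod(C_spline) + psi * tcrossprod(Z)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
    -0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
              (n - p) * log(drop(t(y) %*% P %*% y)))
  }
  # recover the conditioned spline ratio the engine estimated, then compare
  # the profile difference at the engine's scale
  lam_grid <- exp(seq(-4, 8, length.out = 60))
  ll0 <- vapply(lam_grid, reml_dense, numeric(1), psi = 1e-12)
  lam_hat <- lam_grid[which.max(ll0)]
  psi_grid <- exp(seq(-8, 8, length.out = 120))
  ll1 <- vapply(psi_grid, function(ps) reml_dense(lam_hat, ps), numeric(1))
  dense_stat <- max(0, 2 * (max(ll1) - max(ll0)))
  expect_lt(abs(r$statistic - dense_stat), 0.05 * max(1, dense_stat))
})
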