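make_surveys <- function(seed = 1, n_nests = 20, years = 8,
                         propensity_sd = 0.15) {
  set.seed(seed)
  nest_profiles(
    sprintf("N%03d", seq_len(n_nests)),
    exposure_amplitude = 15,
    size_holes = sample(5:60, n_nests, replace = TRUE),
    trail_propensity = rnorm(n_nests, 0, propensity_sd)
  ) |>
    simulate_surveys(trend = "flat", years = years, seed = seed)
}

test_that("identical trail counts give identical standardized effort", {
  sv <- tidyr::expand_grid(nest_id = sprintf("N%02d", 1:12),
                           year = 2015:2020) |>
    dplyr::mutate(
      entrance_holes = rep(seq(10, 54, by = 4), each = 6),
      n_foraging_trails = 2L, n_tree_trails = 1L, n_connection_trails = 0L
    )
  eff <- suppressWarnings(standardize_effort(sv))
  expect_lt(diff(range(eff$standardized_trails)), 1e-6)
  expect_equal(eff$standardized_trails[1], 3, tolerance = 1e-6)
})

test_that("doubling every trail count doubles every standardized estimate", {
  sv <- make_surveys(seed = 5)
  eff1 <- suppressWarnings(standardize_effort(sv))
  sv2 <- dplyr::mutate(sv, n_foraging_trails = 2L * n_foraging_trails,
                       n_tree_trails = 2L * n_tree_trails)
  eff2 <- suppressWarnings(standardize_effort(sv2))
  m <- dplyr::inner_join(eff1, eff2, by = "nest_id")
  expect_equal(m$standardized_trails.y / m$standardized_trails.x,
               rep(2, nrow(m)), tolerance = 1e-4)
})

test_that("known effort offsets are recovered in rank order", {
  set.seed(77)
  prof <- nest_profiles(sprintf("N%03d", 1:60), exposure_amplitude = 15,
                        size_holes = sample(5:60, 60, TRUE),
                        trail_propensity = rnorm(60, 0, 0.15))
  sv <- simulate_surveys(prof, trend = "flat", years = 10, seed = 77)
  eff <- standardize_effort(sv)
  m <- dplyr::inner_join(eff, prof, by = "nest_id")
  expect_gte(cor(m$standardized_trails, m$trail_propensity,
                 method = "spearman"), 0.9)
})

test_that("standardized effort is invariant to row order", {
  sv <- make_surveys(seed = 9)
  eff1 <- standardize_effort(sv)
  set.seed(1)
  eff2 <- standardize_effort(sv[sample(nrow(sv)), ])
  expect_equal(dplyr::arrange(eff1, nest_id),
               dplyr::arrange(eff2, nest_id), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("zero-trail nest-years follow the stated policy", {
  sv <- make_surveys(seed = 11)
  sv$n_foraging_trails[3] <- 0L
  sv$n_tree_trails[3] <- 0L
  w <- testthat::capture_warnings(standardize_effort(sv))
  expect_true(any(grepl("zero-trail", w)))
  eff <- suppressWarnings(standardize_effort(sv, zero_policy = "add1"))
  expect_equal(nrow(eff), length(unique(sv$nest_id)))
})

test_that("compensation trends recover the generating signs", {
  set.seed(13)
  hours <- runif(12, 2, 14)
  nests <- tibble::tibble(
    nest_id = sprintf("N%02d", 1:12),
    mean_size = 5 + 3 * hours + rnorm(12, 0, 2),
    standardized_trails = 8 - 0.4 * hours + rnorm(12, 0, 0.3),
    hours_summer = hours,
    hours_winter = hours / 3
  )
  ct <- compensation_test(nests)
  expect_equal(nrow(ct), 4)
  expect_gt(ct$slope[ct$response == "mean_size" & ct$season == "summer"], 0)
  expect_lt(ct$slope[ct$response == "standardized_trails" &
                       ct$season == "summer"], 0)
  # constant hours are reported as degenerate rather than fitted
  nests$hours_winter <- 4
  ct2 <- compensation_test(nests)
  expect_true(all(ct2$degenerate[ct2$season == "winter"]))
  expect_error(compensation_test(nests[1:2, ]), "fewer than 3")
})

test_that("an exact declining line selects the linear growth model", {
  sz <- tibble::tibble(year = 2015:2019, entrance_holes = c(10, 8, 6, 4, 2))
  g <- suppressWarnings(suppressMessages(fit_growth_models(sz)))
  expect_false("quadratic" %in% g$model) # AICc undefined at n = 5
  lin <- g[g$model == "linear", ]
  expect_equal(lin$delta_aicc, 0)
  expect_lt(lin$t_years, -1e6)
  expect_true(lin$supported)
  expect_message(suppressWarnings(fit_growth_models(sz)), "quadratic")
})

test_that("a constant series selects the no-change model", {
  sz <- tibble::tibble(year = 2015:2024, entrance_holes = 30L)
  g <- suppressMessages(fit_growth_models(sz))
  expect_equal(g$model, "intercept")
  expect_equal(g$delta_aicc, 0)
})

test_that("AICc exceeds AIC and the gap shrinks with sample size", {
  set.seed(17)
  gaps <- vapply(c(6, 10, 20, 50), function(n) {
    d <- data.frame(yr = seq_len(n))
    d$entrance_holes <- 30 + 0.5 * d$yr + rnorm(n, 0, 2)
    f <- lm(entrance_holes ~ yr, data = d)
    nestherm:::aicc(f) - AIC(f)
  }, numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) < 0))
})

test_that("growth-model selection recovers the generating trend", {
  shapes <- rep(c("flat", "linear", "quadratic"), length.out = 30)
  prof <- nest_profiles(sprintf("N%02d", 1:30), exposure_amplitude = 15,
                        size_holes = 30)
  sv <- simulate_surveys(prof, trend = shapes, years = 10, seed = 19)
  g <- fit_growth_models(sv)
  best <- g |>
    dplyr::group_by(nest_id) |>
    dplyr::slice_min(aicc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  truth <- dplyr::distinct(sv, nest_id, trend)
  m <- dplyr::inner_join(best, truth, by = "nest_id")
  hit <- (m$trend == "flat" & m$model == "intercept") | (m$model == m$trend)
  expect_gte(mean(hit), 0.8)
  # dropping years re-runs the reduced series
  g2 <- fit_growth_models(sv[sv$nest_id == "N01", ], drop_years = 2015)
  expect_equal(unique(g2$n_years), 9)
})
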