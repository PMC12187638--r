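test_that("the peak of a symmetric curve is found at its centre", {
  f <- gaussian_curve_fit(peak = 30, sd = 3)
  pk <- find_peak(f)
  expect_false(pk$boundary)
  expect_lt(abs(pk$peak_temp - 30), 0.1 + 1e-9)
})

test_that("a monotone fit yields a flagged boundary peak and no window", {
  d <- data.frame(surface_temp = seq(10, 40, length.out = 100))
  d$y <- 0.1 * d$surface_temp
  f <- fit_additive(d, "y", smooths = list(smooth_spec("surface_temp")))
  pk <- find_peak(f)
  expect_true(pk$boundary)
  expect_warning(ow <- optimal_window(f), "boundary")
  expect_true(is.na(ow$optimal_lo))
})

test_that("coarse-grid argmax agrees with a 0.01-degree brute-force scan", {
  f <- gaussian_curve_fit(peak = 27.3, sd = 4)
  pk <- find_peak(f, grid_step = 0.1)
  r <- f$train_range$surface_temp
  fine <- seq(r[1], r[2], by = 0.01)
  brute <- fine[which.max(predict(f, data.frame(surface_temp = fine)))]
  expect_lt(abs(pk$peak_temp - brute), 0.1 + 1e-9)
})

test_that("fraction one collapses the optimal window onto the peak", {
  f <- gaussian_curve_fit()
  ow <- optimal_window(f, fraction = 1)
  expect_lte(ow$optimal_hi - ow$optimal_lo, 0.2 + 1e-9)
  expect_error(optimal_window(f, fraction = 0), "\\(0, 1\\]")
  expect_error(optimal_window(f, fraction = 1.2), "\\(0, 1\\]")
})

test_that("shrinking the fraction widens the optimal window monotonically", {
  f <- gaussian_curve_fit()
  widths <- vapply(c(0.95, 0.9, 0.7, 0.5), function(fr) {
    ow <- optimal_window(f, fraction = fr)
    ow$optimal_hi - ow$optimal_lo
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("observed-range emergence window equals the active min and max", {
  obs <- tibble::tibble(surface_temp = 20, worker_count = 3L)
  expect_equal(unlist(emergence_window(obs)[, 1:2], use.names = FALSE),
               c(20, 20))
  # the field emergence range printed for trail activity
  obs2 <- tibble::tibble(
    surface_temp = c(15.9, 18, 25, 33.3, 43.1, 12, 47),
    worker_count = c(2L, 5L, 9L, 4L, 1L, 0L, 0L)
  )
  ew <- emergence_window(obs2)
  expect_equal(ew$emergence_lo, 15.9)
  expect_equal(ew$emergence_hi, 43.1)
  expect_error(emergence_window(obs2[obs2$worker_count == 0, ]), "no active")
})

test_that("emergence window matches a brute-force scan on random tables", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:80, 1)
    obs <- tibble::tibble(
      surface_temp = round(runif(n, 0, 50), 1),
      worker_count = rpois(n, 1)
    )
    if (all(obs$worker_count == 0)) obs$worker_count[1] <- 1L
    ew <- emergence_window(obs)
    act <- obs$surface_temp[obs$worker_count > 0]
    expect_equal(ew$emergence_lo, min(act))
    expect_equal(ew$emergence_hi, max(act))
  }
})

test_that("upper-threshold estimates use the max-emerged and median-non-emerged rules", {
  obs <- tibble::tibble(
    surface_temp = c(40, 44, 47.7, 37.3, 42.2, 47.4),
    emerged = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  ut <- upper_threshold_estimates(obs)
  expect_equal(ut$liberal, 47.7)
  expect_equal(ut$conservative, 42.2)
  # liberal below every non-emergence temperature is flagged consistent
  obs2 <- tibble::tibble(surface_temp = c(35, 36, 40, 42, 45),
                         emerged = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(upper_threshold_estimates(obs2)$consistent)
  expect_message(
    ut3 <- upper_threshold_estimates(
      tibble::tibble(surface_temp = c(40, 42), emerged = TRUE)
    ),
    "conservative estimate unavailable"
  )
  expect_true(is.na(ut3$conservative))
  # median equals a sort-based oracle on random inputs
  set.seed(15)
  for (i in 1:20) {
    temps <- runif(sample(3:30, 1), 30, 50)
    ut <- upper_threshold_estimates(
      tibble::tibble(surface_temp = temps, emerged = FALSE)
    )
    s <- sort(temps)
    n <- length(s)
    oracle <- if (n %% 2 == 1) s[(n + 1) / 2] else mean(s[n / 2 + 0:1])
    expect_equal(ut$conservative, oracle)
  }
})

test_that("degenerate hurdle inputs are rejected", {
  obs <- tibble::tibble(nest_id = "A", surface_temp = 25,
                        worker_count = 5L)[rep(1, 40), ]
  expect_error(fit_hurdle(obs), "both zero and positive")
  obs$worker_count <- 0L
  expect_error(fit_hurdle(obs), "both zero and positive")
  expect_error(fit_hurdle(obs[1:10, ]), "at least 30")
  expect_error(fit_hurdle(dplyr::select(obs, -worker_count)),
               "missing columns")
})

test_that("the hurdle curve recovers the generating peak and obeys its invariants", {
  act <- census_activity(seed = 31)
  h <- fit_hurdle(act, "primary")
  pred <- predict(h)
  expect_true(all(pred$combined >= 0))
  expect_true(all(pred$combined <= pred$conditional + 1e-9))
  expect_true(all(pred$presence > 0 & pred$presence < 1))
  pk <- find_peak(h)
  expect_lt(abs(pk$peak_temp - 30), 1)
  # temperature smooth EDF stays inside [1, k - 1]
  for (part in list(h$presence_fit, h$count_fit)) {
    edf <- part$edf_per_term[["s(surface_temp)"]]
    expect_gte(edf, 1 - 1e-6)
    expect_lte(edf, 4 + 1e-6)
  }
})

test_that("primary and adjusted curves agree on unconfounded synthetic data", {
  act <- census_activity(seed = 32)
  h1 <- fit_hurdle(act, "primary")
  h2 <- fit_hurdle(act, "adjusted")
  expect_lt(abs(find_peak(h1)$peak_temp - find_peak(h2)$peak_temp), 1)
})

test_that("performance windows nest as emergence >= optimal >= peak", {
  act <- census_activity(seed = 33)
  h <- fit_hurdle(act, "primary")
  w <- performance_window(h, act, "foraging")
  expect_lte(w$emergence_lo, w$optimal_lo)
  expect_lte(w$optimal_lo, w$peak_temp)
  expect_lte(w$peak_temp, w$optimal_hi)
  expect_lte(w$optimal_hi, w$emergence_hi)
})
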