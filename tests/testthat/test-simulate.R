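test_that("zero amplitude and zero noise give the bare baseline cycle", {
  prof <- nest_profiles("N1", exposure_amplitude = 0, seasonal_amplitude = 0)
  cfg <- sim_config(date_range = as.Date(c("2019-02-01", "2019-02-05")),
                    noise_sd = 0)
  ser <- simulate_temperature_series(prof, cfg)
  doy <- as.integer(strftime(as.Date(ser$timestamp), "%j"))
  baseline <- cfg$base_temp + cfg$base_seasonal_amplitude * seasonal_index(doy)
  expect_equal(ser$temp_c, baseline)
})

test_that("noiseless nests share identical daily minima and exposure-ordered ranges", {
  qs <- quiet_series(n_nests = 3, to = "2019-01-20")
  daily <- qs$series |>
    dplyr::mutate(date = as.Date(timestamp)) |>
    dplyr::group_by(nest_id, date) |>
    dplyr::summarise(mn = min(temp_c), rng = max(temp_c) - min(temp_c),
                     .groups = "drop")
  wide_min <- tidyr::pivot_wider(dplyr::select(daily, -rng),
                                 names_from = nest_id, values_from = mn)
  mins <- as.matrix(wide_min[, -1])
  expect_equal(apply(mins, 1, max), apply(mins, 1, min))
  rng_by_nest <- daily |>
    dplyr::group_by(nest_id) |>
    dplyr::summarise(m = mean(rng)) |>
    dplyr::arrange(match(nest_id, qs$profiles$nest_id))
  expect_true(all(diff(rng_by_nest$m) > 0)) # amplitudes increase across nests
})

test_that("noiseless daily maximum matches the closed form at solar noon", {
  qs <- quiet_series(n_nests = 2, to = "2019-01-15")
  prof <- qs$profiles
  cfg <- qs$config
  for (d in as.list(as.Date(c("2019-01-03", "2019-01-12")))) {
    doy <- as.integer(strftime(d, "%j"))
    for (j in 1:2) {
      expected <- cfg$base_temp +
        cfg$base_seasonal_amplitude * seasonal_index(doy) +
        prof$exposure_amplitude[j] +
        prof$seasonal_amplitude[j] * seasonal_index(doy)
      got <- max(qs$series$temp_c[qs$series$nest_id == prof$nest_id[j] &
                                    as.Date(qs$series$timestamp) == d])
      expect_equal(got, expected)
    }
  }
})

test_that("generators are byte-identical under a fixed seed", {
  prof <- default_nest_profiles(3)
  cfg <- sim_config(date_range = as.Date(c("2019-01-01", "2019-01-31")),
                    seed = 99)
  s1 <- simulate_temperature_series(prof, cfg)
  s2 <- simulate_temperature_series(prof, cfg)
  expect_identical(s1, s2)
  a1 <- simulate_activity(s1, true_curve_spec(), prof, seed = 7)
  a2 <- simulate_activity(s2, true_curve_spec(), prof, seed = 7)
  expect_identical(a1, a2)
  v1 <- simulate_surveys(prof, trend = "linear", seed = 3)
  v2 <- simulate_surveys(prof, trend = "linear", seed = 3)
  expect_identical(v1, v2)
})

test_that("activity is absent far below the lower presence midpoint", {
  # a fully shaded nest in mid-winter never warms past ~8 C
  prof <- nest_profiles("N1", exposure_amplitude = 0, seasonal_amplitude = 0,
                        size_holes = 30)
  cfg <- sim_config(date_range = as.Date(c("2019-07-10", "2019-07-20")),
                    noise_sd = 0)
  ser <- simulate_temperature_series(prof, cfg)
  act <- simulate_activity(ser, true_curve_spec(), prof,
                           dates = as.Date("2019-07-15"), seed = 5)
  expect_lt(max(act$surface_temp), 10)
  expect_true(all(act$worker_count == 0))
})

test_that("mean count at the curve peak matches the analytic hurdle mean", {
  curve <- true_curve_spec()
  n_nests <- 800
  prof <- nest_profiles(paste0("N", seq_len(n_nests)),
                        exposure_amplitude = 15, size_holes = 30)
  d <- as.Date("2019-01-15")
  ts <- as.POSIXct(paste(d, sprintf("%02d:00:00", 6:18)), tz = "UTC")
  ser <- tibble::tibble(
    nest_id = rep(prof$nest_id, each = length(ts)),
    timestamp = rep(ts, n_nests),
    temp_c = curve$peak_temp
  )
  act <- simulate_activity(ser, curve, prof, dates = d, seed = 21)
  expect_gt(nrow(act), 5000)
  expected <- true_presence(curve, curve$peak_temp) * curve$max_rate
  se <- stats::sd(act$worker_count) / sqrt(nrow(act))
  expect_lt(abs(mean(act$worker_count) - expected), 3 * se)
})

test_that("swarm speeds follow the unimodal curve when workers emerge", {
  qs <- quiet_series(n_nests = 3, from = "2019-01-01", to = "2019-12-31",
                     noise_sd = 1)
  sw <- simulate_activity(qs$series, true_curve_spec(), qs$profiles,
                          response = "speed", seed = 9)
  expect_true(all(c("swarm_speed", "emerged") %in% names(sw)))
  expect_true(all(sw$swarm_speed >= 0))
  expect_true(all(sw$swarm_speed[!sw$emerged] == 0))
})

test_that("survey trends follow the stated arithmetic without noise", {
  prof <- nest_profiles(c("A", "B"), exposure_amplitude = 10,
                        size_holes = c(40, 40))
  flat <- simulate_surveys(prof, trend = "flat", years = 10, noise_frac = 0,
                           seed = 1)
  expect_true(all(tapply(flat$entrance_holes, flat$nest_id,
                         function(x) length(unique(x))) == 1))
  tr <- tibble::tibble(nest_id = c("A", "B"), slope = c(-3, 0), quad = 0)
  lin <- simulate_surveys(prof, trend = tr, years = 10, noise_frac = 0,
                          seed = 1)
  a <- lin[lin$nest_id == "A", ]
  expect_equal(a$entrance_holes[10], a$entrance_holes[1] - 27)
})

test_that("invalid generator inputs are rejected", {
  prof <- default_nest_profiles(2)
  expect_error(simulate_temperature_series(prof[0, ], sim_config()),
               "non-empty")
  expect_error(sim_config(date_range = as.Date(c("2019-02-01", "2019-01-01"))),
               "ascending")
  expect_error(sim_config(cadence = 7), "divisor")
  expect_error(sim_config(noise_autocorrelation = 1), "\\[0, 1\\)")
  expect_error(simulate_surveys(prof, years = 2), "at least 3")
  expect_error(nest_profiles("A", exposure_amplitude = -1), "non-negative")
  expect_error(true_curve_spec(peak_temp = 50), "bracket")
  qs <- quiet_series()
  expect_error(
    simulate_activity(qs$series, true_curve_spec(), qs$profiles,
                      dates = as.Date("2030-01-01")),
    "outside the series range"
  )
})
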