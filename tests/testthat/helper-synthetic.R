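# shared fixtures, all generated in code

# a short noiseless two-nest winter/summer-spanning series
quiet_series <- function(n_nests = 2, from = "2019-01-01", to = "2019-01-10",
                         noise_sd = 0, seed = 1) {
  prof <- nest_profiles(paste0("N", seq_len(n_nests)),
                        exposure_amplitude = seq(10, 20,
                                                 length.out = n_nests),
                        seasonal_amplitude = 5)
  cfg <- sim_config(date_range = as.Date(c(from, to)), noise_sd = noise_sd,
                    seed = seed)
  list(profiles = prof, config = cfg,
       series = simulate_temperature_series(prof, cfg))
}

# hand-built single-nest series at 30-min cadence with given temps per day
flat_series <- function(temp = 20, dates = as.Date("2019-03-01"),
                        nest_id = "NX") {
  ts <- as.POSIXct(unlist(lapply(dates, function(d) {
    seq(as.POSIXct(paste(d, "00:00:00"), tz = "UTC"), by = 1800,
        length.out = 48)
  })), tz = "UTC", origin = "1970-01-01")
  tibble::tibble(nest_id = nest_id, timestamp = ts,
                 temp_c = rep(temp, length.out = length(ts)))
}

# 237-observation activity sample mirroring an 11-nest two-day census
census_activity <- function(seed, curve = true_curve_spec(), n_obs = 237) {
  profs <- default_nest_profiles(11)
  cfg <- sim_config(seed = seed,
                    date_range = as.Date(c("2019-01-01", "2019-12-31")))
  ser <- simulate_temperature_series(profs, cfg)
  act <- simulate_activity(ser, curve, profs, seed = seed + 100)
  set.seed(seed + 200)
  act[sample(nrow(act), min(n_obs, nrow(act))), ]
}

# noiseless Gaussian-shaped activity curve as an interpolating additive fit
gaussian_curve_fit <- function(peak = 30, sd = 3, lo = 10, hi = 50, n = 400,
                               k = 15) {
  d <- data.frame(surface_temp = seq(lo, hi, length.out = n))
  d$y <- exp(-(d$surface_temp - peak)^2 / (2 * sd^2))
  fit_additive(d, "y", smooths = list(smooth_spec("surface_temp", k = k)),
               sp = 1e-9)
}
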