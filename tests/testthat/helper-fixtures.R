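# Shared fixture builders: everything is generated in code at test time.

fixture_schedule <- function(n_ld_days = 2) {
  light_schedule(lights_on_hour = 8, lights_off_hour = 20,
                 n_ld_days = n_ld_days)
}

# Deterministic series with explicit counts, starting at lights-on.
fixture_series <- function(counts, bin_width = 60, n_ld_days = 0,
                           fly_id = "fx") {
  sch <- fixture_schedule(n_ld_days)
  activity_series(fly_id,
                  as.POSIXct("2024-01-01 08:00:00", tz = "UTC"),
                  bin_width, counts, schedule = sch)
}

# A strongly rhythmic simulated fly, DD only, 15-min bins.
fixture_rhythmic_fly <- function(period_h = 24, n_dd_days = 9, seed = 42,
                                 amplitude = 2, ...) {
  p <- fly_params(period_h = period_h, amplitude = amplitude, seed = seed,
                  ...)
  bin_series(simulate_fly(p, fixture_schedule(0), n_ld_days = 0,
                          n_dd_days = n_dd_days), 15)
}

fixture_null_fly <- function(n_dd_days = 9, seed = 7, baseline_rate = 1) {
  p <- fly_params(arrhythmic = TRUE, baseline_rate = baseline_rate,
                  seed = seed)
  bin_series(simulate_fly(p, fixture_schedule(0), n_ld_days = 0,
                          n_dd_days = n_dd_days), 15)
}

# Lomb-Scargle oracle: least-squares sinusoid fit at one period; power =
# reduction in sum of squares / (2 * sample variance).
ls_fit_oracle <- function(x, t_h, period) {
  w <- 2 * pi / period
  fit <- stats::lm(x ~ cos(w * t_h) + sin(w * t_h))
  (sum((x - mean(x))^2) - sum(stats::residuals(fit)^2)) /
    (2 * stats::var(x))
}

# Null-calibrated rhythmicity config shared across tests (computed once).
calibrated_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- rhythm_config(
        delta_threshold = as.numeric(
          calibrate_delta_threshold(n_flies = 200, seed = 11)))
    cache
  }
})
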