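test_that("generators are pure functions of their seed", {
  a <- simulate_fly(fly_params(seed = 9), n_ld_days = 1, n_dd_days = 1)
  b <- simulate_fly(fly_params(seed = 9), n_ld_days = 1, n_dd_days = 1)
  expect_identical(a$counts, b$counts)
  ca <- simulate_cohort(cohort_spec(n_flies = 3, master_seed = 5,
                                    n_dd_days = 1))
  cb <- simulate_cohort(cohort_spec(n_flies = 3, master_seed = 5,
                                    n_dd_days = 1))
  expect_identical(lapply(ca, `[[`, "counts"), lapply(cb, `[[`, "counts"))
  t1 <- simulate_timecourse(seed = 3)
  t2 <- simulate_timecourse(seed = 3)
  expect_identical(t1, t2)
})

test_that("flat fly total counts match Poisson moments", {
  p <- fly_params(baseline_rate = 0.1, arrhythmic = TRUE, seed = 21)
  s <- simulate_fly(p, n_ld_days = 0, n_dd_days = 1)
  total <- sum(s$counts)
  # total ~ Poisson(144): mean 144, sd 12
  expect_lt(abs(total - 144), 3 * 12)
})

test_that("implanted activity phase is recovered by circular mean", {
  p <- fly_params(amplitude = 2, period_h = 24, seed = 33)
  s <- simulate_fly(p, n_ld_days = 0, n_dd_days = 9)
  ang <- 2 * pi * s$phase / 24
  obs <- Arg(sum(s$counts * exp(1i * ang)))
  # oracle: the same circular mean on the deterministic rate profile
  lam <- expected_rate(p, (seq_along(s$counts) - 1) / 60)
  truth <- Arg(sum(lam * exp(1i * ang)))
  dh <- (obs - truth) * 24 / (2 * pi)
  expect_lt(abs((dh + 12) %% 24 - 12), 1)
})

test_that("cohort jitter averages out and zero jitter gives clones", {
  spec <- cohort_spec(n_flies = 40, period_jitter_sd = 0.3,
                      master_seed = 8, n_dd_days = 1)
  periods <- vapply(seq_len(spec$n_flies), function(i) {
    jit <- circadam:::with_seed(circadam:::derive_seed(8, i, salt = 77L),
                                stats::rnorm(2))
    spec$params$period_h + jit[1] * 0.3
  }, 1)
  expect_lt(abs(mean(periods) - 24), 3 * 0.3 / sqrt(40))
  z <- simulate_cohort(cohort_spec(n_flies = 3, period_jitter_sd = 0,
                                   phase_jitter_sd = 0, master_seed = 2,
                                   n_dd_days = 1))
  expect_error(cohort_spec(n_flies = 0), "positive")
  expect_length(z, 3)
})

test_that("timecourse generator hits its cosine mean and noise CV", {
  flat <- simulate_timecourse(rel_amplitude = 0, noise_cv = 0)
  expect_true(all(flat$value == 1))
  exact <- simulate_timecourse(rel_amplitude = 0.4, noise_cv = 0,
                               acrophase_ct = 5, mesor = 2)
  expect_equal(exact$value,
               2 * (1 + 0.4 * cos(2 * pi * (exact$ct - 5) / 24)))
  big <- simulate_timecourse(rel_amplitude = 0, noise_cv = 0.2,
                             timepoints = 1:8, n_replicates = 250,
                             seed = 12)
  expect_equal(sd(big$value) / mean(big$value), 0.2, tolerance = 0.05)
  expect_error(simulate_timecourse(noise_cv = -1), "noise_cv")
})

test_that("arrhythmic flag nulls out every rhythm-bearing term", {
  p <- fly_params(amplitude = 3, anticipation_ramp = "both", ramp_gain = 2,
                  arrhythmic = TRUE)
  expect_equal(p$amplitude, 0)
  expect_equal(p$ramp_gain, 0)
  lam <- expected_rate(p, seq(0, 48, by = 0.25))
  expect_true(all(lam == p$baseline_rate))
})

test_that("synthetic nucleus images implant exact means and background", {
  img <- simulate_nucleus_image(5, intensities = c(50, 60, 70, 80, 90),
                                background_level = 10, noise_sd = 0,
                                seed = 3)
  for (k in 1:5)
    expect_equal(mean(img$image[img$masks == k]), c(50, 60, 70, 80, 90)[k])
  expect_equal(mean(img$image[img$masks == 0]), 10)
  expect_error(simulate_nucleus_image(500, dim = c(32, 32), seed = 1),
               "density|place")
})
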