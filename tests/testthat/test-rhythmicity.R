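test_that("strong rhythmic flies are called rhythmic with accurate periods", {
  cfg <- calibrated_config()
  for (tau in c(23.5, 24.5)) {
    s <- fixture_rhythmic_fly(period_h = tau, seed = 200 + tau * 2)
    call <- classify_fly(s, cfg)
    expect_equal(call$automated_class, "rhythmic")
    expect_lt(abs(call$period_h - tau), 0.25 + 1e-9)
  }
})

test_that("flat Poisson flies are arrhythmic with rhythm power floored at 0", {
  cfg <- calibrated_config()
  calls <- lapply(1:8, function(i)
    classify_fly(fixture_null_fly(seed = 900 + i), cfg))
  classes <- vapply(calls, `[[`, "", "automated_class")
  expect_gte(sum(classes == "arrhythmic"), 7)
  raw <- vapply(calls, `[[`, 1, "cs_power_raw")
  rep_ <- vapply(calls, `[[`, 1, "cs_power_reported")
  expect_true(all(rep_[raw < 0] == 0))
  expect_true(all(rep_[raw > 0] == raw[raw > 0]))
  expect_true(all(rep_ >= 0))
})

test_that("raising the cutoff never converts arrhythmic to rhythmic", {
  s <- fixture_rhythmic_fly(seed = 41)
  thresholds <- c(-Inf, 0, 5, 50, 1e6)
  cls <- vapply(thresholds, function(th)
    classify_fly(s, rhythm_config(delta_threshold = th))$automated_class,
    "")
  expect_equal(cls[1], "rhythmic")   # -Inf cutoff: everything rhythmic
  r <- cls == "rhythmic"
  expect_true(all(diff(as.integer(r)) <= 0))   # monotone in the cutoff
})

test_that("classification preconditions are enforced", {
  expect_error(classify_fly(fixture_rhythmic_fly(n_dd_days = 4)),
               "too short")
  one_min <- simulate_fly(fly_params(seed = 2), n_ld_days = 0, n_dd_days = 9)
  expect_error(classify_fly(one_min), "15-min")
})

test_that("sustained rhythmicity needs both halves rhythmic with matching period", {
  cfg <- calibrated_config()
  expect_true(sustained_rhythmicity(fixture_rhythmic_fly(seed = 51), cfg))
  damped <- fixture_rhythmic_fly(seed = 52, damping_per_day = 0.55)
  expect_false(sustained_rhythmicity(damped, cfg))
  expect_false(sustained_rhythmicity(fixture_null_fly(seed = 53), cfg))
  expect_error(sustained_rhythmicity(fixture_rhythmic_fly(n_dd_days = 7),
                                     cfg), "8 days")
})

test_that("cohort summaries count categories and apply the 10% merge rule", {
  mk <- function(delta, period = 24) {
    structure(list(fly_id = "x", ls_delta = delta, cs_power_raw = 1,
                   cs_power_reported = 1, period_h = period,
                   automated_class = if (delta > 10) "rhythmic"
                   else "arrhythmic",
                   sustained = NA, delta_threshold = 10),
              class = "rhythm_call")
  }
  all_r <- summarize_cohort(replicate(10, mk(100), simplify = FALSE))
  expect_equal(all_r$pct_rhythmic, 100)
  expect_equal(all_r$pct_arrhythmic, 0)

  # 9 strong + 1 weak: weak is exactly 10%, not < 10% -> kept separate
  ten <- summarize_cohort(c(replicate(9, mk(100), simplify = FALSE),
                            list(mk(15))))
  expect_equal(ten$pct_weakly_rhythmic, 10)
  expect_false(ten$weak_merged)

  # 1 weak of 20 (5% < 10%) -> merged into rhythmic
  twenty <- summarize_cohort(c(replicate(19, mk(100), simplify = FALSE),
                               list(mk(15))))
  expect_equal(twenty$pct_weakly_rhythmic, 0)
  expect_equal(twenty$pct_rhythmic, 100)
  expect_true(twenty$weak_merged)

  mixed <- summarize_cohort(c(replicate(4, mk(100, 24), simplify = FALSE),
                              replicate(4, mk(5), simplify = FALSE)))
  expect_equal(mixed$pct_rhythmic + mixed$pct_weakly_rhythmic +
                 mixed$pct_arrhythmic, 100)
  expect_equal(mixed$period_mean_h, 24)   # over rhythmic flies only
  expect_error(summarize_cohort(list()), "empty")
})

test_that("period recovery across implanted periods stays within a grid step", {
  cfg <- calibrated_config()
  taus <- c(23.0, 24.0)
  for (tau in taus) {
    errs <- vapply(1:6, function(i) {
      s <- fixture_rhythmic_fly(period_h = tau, seed = 3000 + 10 * tau + i)
      abs(classify_fly(s, cfg)$period_h - tau)
    }, 1)
    expect_lte(median(errs), 0.25)
  }
})
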