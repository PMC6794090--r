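test_that("LS power equals the least-squares sinusoid-fit statistic", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rpois(96 * 3, 5) + 2 * sin(2 * pi * seq_len(96 * 3) / 96)
    s <- fixture_series(pmax(x, 0), bin_width = 15)
    pg <- ls_periodogram(s)
    t_h <- (seq_along(s$counts) - 1) * 0.25
    for (p in sample(pg$periods_h, 4))
      expect_equal(pg$stat[which(pg$periods_h == p)],
                   ls_fit_oracle(s$counts, t_h, p), tolerance = 1e-10)
  }
})

test_that("LS finds a noiseless sinusoid's period on the grid", {
  t_h <- (seq_len(9 * 96) - 1) * 0.25
  s <- fixture_series(10 + 5 * cos(2 * pi * t_h / 24), bin_width = 15)
  pg <- ls_periodogram(s)
  expect_equal(pg$peak_period_h, 24, tolerance = 0.25)
  expect_gt(pg$peak_stat, pg$peak_threshold)
})

test_that("LS power is invariant to offset and scale", {
  s <- fixture_rhythmic_fly(seed = 17, n_dd_days = 3)
  base <- ls_periodogram(s)
  shifted <- s; shifted$counts <- s$counts * 7 + 3
  expect_equal(ls_periodogram(shifted)$stat, base$stat, tolerance = 1e-9)
})

test_that("LS threshold follows the independent-frequency formula", {
  s <- fixture_null_fly(n_dd_days = 3)
  pg <- ls_periodogram(s, alpha = 0.01)
  M <- length(pg$periods_h)
  expect_equal(unique(pg$threshold), -log(1 - (1 - 0.01)^(1 / M)))
})

test_that("LS null false-positive rate respects the alpha bound", {
  # peak > threshold should occur with probability <= alpha * M (union bound)
  alpha <- 0.05
  hits <- vapply(1:120, function(i) {
    s <- fixture_null_fly(seed = 5000 + i, n_dd_days = 2)
    pg <- ls_periodogram(s, alpha = alpha)
    pg$peak_stat > pg$peak_threshold
  }, TRUE)
  m <- length(ls_periodogram(fixture_null_fly(n_dd_days = 2))$periods_h)
  bound <- alpha * m
  expect_lte(mean(hits), bound * (1 + 3 / sqrt(120 * bound)))
})

test_that("chi-square periodogram reproduces the hand-worked folding value", {
  s <- fixture_series(rep(c(1, 3), 48), bin_width = 15)
  pg <- cs_periodogram(s, period_range_h = c(0.5, 0.5))
  expect_equal(pg$stat, 96)
  expect_equal(pg$threshold, qchisq(0.999, df = 1))
  expect_equal(pg$peak_stat - pg$peak_threshold, 96 - 10.82757,
               tolerance = 1e-4)
})

test_that("chi-square peak sits at the period of an exactly repeated day", {
  day <- rep(c(rep(0, 48), rep(6, 48)), length.out = 96) + (1:96 %% 7)
  s <- fixture_series(rep(day, 9), bin_width = 15)
  pg <- cs_periodogram(s)
  expect_equal(pg$peak_period_h, 24)
})

test_that("chi-square Q follows chi-squared(P-1) under iid noise", {
  set.seed(99)
  q <- vapply(1:400, function(i) {
    s <- fixture_series(rnorm(240, 50, 5), bin_width = 15)
    cs_periodogram(s, period_range_h = c(2, 2))$stat
  }, 1)
  ks <- suppressWarnings(ks.test(q, pchisq, df = 7))
  expect_gt(ks$p.value, 0.01)
})

test_that("Q_P is invariant to positive affine transforms", {
  s <- fixture_rhythmic_fly(seed = 23, n_dd_days = 3)
  base <- cs_periodogram(s)
  tr <- s; tr$counts <- 2.5 * s$counts + 4
  expect_equal(cs_periodogram(tr)$stat, base$stat, tolerance = 1e-9)
  expect_true(all(base$stat >= 0))
})

test_that("stronger implanted rhythms give larger peaks on matched seeds", {
  for (m in c("ls", "cs")) {
    peaks <- vapply(c(0.5, 1, 2), function(a) {
      s <- fixture_rhythmic_fly(amplitude = a, seed = 77, n_dd_days = 4)
      pg <- if (m == "ls") ls_periodogram(s) else cs_periodogram(s)
      pg$peak_stat
    }, 1)
    expect_true(all(diff(peaks) > 0))
  }
})

test_that("degenerate inputs error clearly", {
  const <- fixture_series(rep(5, 96 * 3), bin_width = 15)
  expect_error(ls_periodogram(const), "constant")
  expect_error(cs_periodogram(const), "constant")
  short <- fixture_series(rep(c(1, 2), 48), bin_width = 15)
  expect_error(ls_periodogram(short), "2 days")
  expect_error(cs_periodogram(short), "2 complete cycles")
  expect_error(ls_periodogram(fixture_rhythmic_fly(n_dd_days = 3),
                              period_range_h = c(20, 19)))
})
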