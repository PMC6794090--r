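# exhaustive permutation oracle for the Kendall S null
enumerate_null <- function(reference) {
  n <- length(reference)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  s <- vapply(perms(seq_len(n)), function(p) kendall_s(p, reference)$S, 1)
  tab <- table(s) / length(s)
  data.frame(S = as.numeric(names(tab)), prob = as.numeric(tab))
}

test_that("reference patterns deduplicate and respect periodicity", {
  tp <- c(1, 5, 9, 13, 17, 21, 25)
  pats <- jtk_reference_patterns(tp, 24, 4)
  expect_lte(length(pats), 6)
  # CT1 and CT25 are one cycle apart: tied in every period-24 pattern
  for (p in pats) expect_equal(p$ranks[1], p$ranks[7])
  # a lag of one full period reproduces lag 0 (9-decimal rounding first,
  # as in the pattern builder, so one-ulp cosine noise cannot break ties)
  r0 <- rank(round(cos(2 * pi * (tp - 0) / 24), 9), ties.method = "average")
  r24 <- rank(round(cos(2 * pi * (tp - 24) / 24), 9),
              ties.method = "average")
  expect_equal(r0, r24)
  expect_error(jtk_reference_patterns(c(1, 1, 1), 24, 4), "distinct")
  expect_error(jtk_reference_patterns(tp, numeric(0), 4), "empty")
})

test_that("kendall_s matches pair enumeration and hits the tau bounds", {
  ks <- kendall_s(c(1, 3, 2), c(1, 2, 3))
  expect_equal(ks$S, 1)   # pairs: (1,3)+, (1,2)+, (3,2)-
  expect_equal(ks$tau, 1 / 3)
  expect_equal(kendall_s(1:5, 1:5)$tau, 1)
  expect_equal(kendall_s(5:1, 1:5)$tau, -1)
  allt <- kendall_s(rep(2, 4), 1:4)
  expect_true(is.na(allt$tau))
  expect_true(attr(allt, "degenerate"))
})

test_that("exact null DP equals exhaustive enumeration", {
  refs <- list(1:3,                 # all distinct
               1:5,                 # spec bound: 5 distinct values
               c(1.5, 1.5, 3, 4),   # one tie pair
               c(1, 1, 2, 2, 3))    # two tie groups
  for (ref in refs) {
    dp <- jtk_exact_null(ref)
    bf <- enumerate_null(ref)
    dp_nz <- dp[dp$prob > 1e-12, ]
    expect_equal(dp_nz$S, bf$S)
    expect_equal(dp_nz$prob, bf$prob, tolerance = 1e-12)
    expect_equal(sum(dp$prob), 1, tolerance = 1e-12)
    expect_equal(dp$prob, rev(dp$prob), tolerance = 1e-12)  # symmetry
  }
})

test_that("exact p agrees with permutation sampling on random instances", {
  set.seed(14)
  for (i in 1:4) {
    ref <- sort(sample(1:4, 8, replace = TRUE))
    x <- rnorm(8)
    s_obs <- kendall_s(x, ref)$S
    p_dp <- jtk_exact_p(s_obs, ref)
    s_mc <- vapply(1:4000, function(j) kendall_s(sample(x), ref)$S, 1)
    p_mc <- mean(abs(s_mc) >= abs(s_obs))
    expect_lt(abs(p_dp - p_mc), 4 * sqrt(p_dp * (1 - p_dp) / 4000) + 0.01)
  }
})

test_that("jtk_cycle recovers a cosine's period and phase", {
  tc <- simulate_timecourse(rel_amplitude = 0.5, noise_cv = 0,
                            acrophase_ct = 8)
  r <- jtk_cycle(tc)
  expect_true(r$rhythmic)
  expect_equal(r$best_period_h, 24)
  expect_lte(abs(r$best_lag_h - 8), 4)
  expect_equal(r$tau, 1)
  # bonferroni bookkeeping
  expect_equal(r$p_adj, min(1, r$p_exact * r$n_alternatives))
})

test_that("tau is invariant to monotone transforms and replicate order", {
  tc <- simulate_timecourse(rel_amplitude = 0.4, noise_cv = 0.1, seed = 5)
  r1 <- jtk_cycle(tc)
  tc2 <- tc; tc2$value <- exp(tc$value)
  r2 <- jtk_cycle(tc2)
  expect_equal(r1$tau, r2$tau)
  expect_equal(r1$p_exact, r2$p_exact)
  tc3 <- tc[sample(nrow(tc)), ]
  r3 <- jtk_cycle(tc3)
  expect_equal(r1$tau, r3$tau)
  expect_equal(r1$best_lag_h, r3$best_lag_h)
})

test_that("flat time courses keep the type-I error near alpha", {
  hits <- vapply(1:200, function(i) {
    tc <- simulate_timecourse(rel_amplitude = 0, noise_cv = 0.2,
                              seed = 7000 + i)
    jtk_cycle(tc)$rhythmic
  }, TRUE)
  alpha <- 0.05
  expect_lte(mean(hits), alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
  const <- jtk_cycle(simulate_timecourse(rel_amplitude = 0, noise_cv = 0))
  expect_false(const$rhythmic)
  expect_true(const$degenerate)
})

test_that("jtk_table scores genes independently", {
  df <- rbind(simulate_timecourse(rel_amplitude = 0.5, noise_cv = 0.1,
                                  acrophase_ct = 8, gene = "tim", seed = 1),
              simulate_timecourse(rel_amplitude = 0, noise_cv = 0.2,
                                  gene = "acp", seed = 2))
  tab <- jtk_table(df)
  expect_setequal(tab$gene, c("tim", "acp"))
  expect_true(tab$rhythmic[tab$gene == "tim"])
  expect_false(tab$rhythmic[tab$gene == "acp"])
})
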