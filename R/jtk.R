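#' Cosine reference rank patterns for the JTK test
#'
#' For each candidate (period, phase-lag) pair, the reference waveform is
#' `cos(2 pi (t - lag) / period)` evaluated at the sampled timepoints, and
#' only its rank ordering (with ties) matters. Timepoints are taken mod the
#' period, so samples one full cycle apart (e.g. CT1 and CT25) share a
#' phase. Duplicate patterns arising from different (period, lag) pairs are
#' deduplicated, keeping the first (shortest period, earliest lag).
#'
#' @param timepoints Sampled times in hours (>= 3 distinct values).
#' @param periods_h Candidate periods in hours (non-empty).
#' @param lag_step_h Phase-lag grid step in hours.
#' @return A list of patterns, each `list(period_h, lag_h, ranks)` where
#'   `ranks` are midranks of the reference over `timepoints`.
#' @export
jtk_reference_patterns <- function(timepoints, periods_h = c(20, 24, 28),
                                   lag_step_h = 4) {
  if (length(periods_h) == 0) stop("empty period list")
  if (length(unique(timepoints)) < 3)
    stop("need >= 3 distinct timepoints")
  out <- list()
  seen <- character(0)
  for (p in periods_h) {
    for (lag in seq(0, p - lag_step_h, by = lag_step_h)) {
      ref <- round(cos(2 * pi * (timepoints - lag) / p), 9)
      r <- rank(ref, ties.method = "average")
      key <- paste(r, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- list(period_h = p, lag_h = lag, ranks = r)
      }
    }
  }
  out
}

#' Kendall S statistic and tau against a tied reference pattern
#'
#' `S` sums sign-concordance over all pairs; pairs tied in either vector
#' contribute 0. `tau = S / sqrt((n0 - Tx)(n0 - Tr))` with `n0 = n(n-1)/2`
#' and `Tx`, `Tr` the tied-pair counts of the data and reference -- the
#' maximal attainable `|S|` whenever either vector is tie-free.
#'
#' @param values Numeric data vector.
#' @param reference Reference ranks (may contain ties), same length.
#' @return `list(S, tau, n_pairs)`; `tau` is `NA` (flagged via attribute
#'   `degenerate`) when all values are tied.
#' @export
kendall_s <- function(values, reference) {
  n <- length(values)
  stopifnot(length(reference) == n, n >= 2)
  sv <- sign(outer(values, values, "-"))
  sr <- sign(outer(reference, reference, "-"))
  up <- upper.tri(sv)
  S <- sum(sv[up] * sr[up])
  n0 <- n * (n - 1) / 2
  tx <- n0 - sum(sv[up] != 0)
  tr <- n0 - sum(sr[up] != 0)
  denom <- sqrt((n0 - tx) * (n0 - tr))
  if (denom == 0)
    return(structure(list(S = S, tau = NA_real_, n_pairs = n0),
                     degenerate = TRUE))
  list(S = S, tau = S / denom, n_pairs = n0)
}

# exact polynomial multiplication (no FFT, so tail probabilities stay exact
# to double precision)
.poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Distribution of the pairwise inversion count between a block of n
# exchangeable items and m preceding items. The inversion counts of the n
# block items (old items after each) form a non-increasing sequence in
# {0..m}, so the number of interleavings with total w equals the number of
# partitions of w fitting in an n x m box (the Gaussian binomial
# [m+n, n]_q); computed by the box recurrence
# P(n, m, w) = P(n, m-1, w) + P(n-1, m, w - m), then normalized by
# choose(m+n, n).
.inversion_dist <- function(m, n) {
  len <- m * n + 1
  po <- replicate(n + 1, {z <- numeric(len); z[1] <- 1; z},
                  simplify = FALSE)   # column m' = 0: all ones at w = 0
  for (mp in seq_len(m)) {
    for (i in seq_len(n)) {
      shifted <- numeric(len)
      keep <- seq_len(len - mp)
      shifted[keep + mp] <- po[[i]][keep]
      po[[i + 1]] <- po[[i + 1]] + shifted
    }
  }
  po[[n + 1]] / choose(m + n, n)
}

#' Exact null distribution of Kendall's S against a tied reference
#'
#' Probability mass function of `S` under uniformly random orderings of
#' distinct data values against a fixed reference pattern with tie groups,
#' computed by dynamic-programming convolution over the reference's
#' tie-group structure (pairs within a reference tie group never contribute
#' to `S`; between-group pair concordances decompose into independent
#' interleaving counts). For 28 observations this is exact and effectively
#' instant.
#'
#' @param reference Reference ranks (with ties) of length `n`.
#' @return `data.frame` with columns `S` and `prob`.
#' @export
jtk_exact_null <- function(reference) {
  sizes <- as.integer(table(reference))
  jtk_null_from_sizes(sizes)
}

jtk_null_from_sizes <- function(sizes) {
  if (sum(sizes) > 60)
    stop("exact null limited to <= 60 observations")
  pmf <- 1
  m <- 0
  for (nk in sizes) {
    if (m > 0) pmf <- .poly_mult(pmf, .inversion_dist(m, nk))
    m <- m + nk
  }
  p0 <- length(pmf) - 1                     # max discordant pairs
  data.frame(S = 2 * (0:p0) - p0, prob = pmf)
}

# cache of exact nulls keyed by tie-group signature
.jtk_cache <- new.env(parent = emptyenv())

.jtk_null_cached <- function(reference) {
  sizes <- sort(as.integer(table(reference)))
  key <- paste(sizes, collapse = ".")
  if (is.null(.jtk_cache[[key]]))
    .jtk_cache[[key]] <- jtk_null_from_sizes(sizes)
  .jtk_cache[[key]]
}

#' Two-sided exact p-value for an observed S
#'
#' @param S Observed Kendall S.
#' @param reference Reference ranks the null is conditioned on.
#' @return `P(|S'| >= |S|)` under the exact null.
#' @export
jtk_exact_p <- function(S, reference) {
  null <- .jtk_null_cached(reference)
  sum(null$prob[abs(null$S) >= abs(S) - 1e-9])
}

#' JTK-Cycle rhythmicity test for an expression time course
#'
#' Nonparametric test for rhythmic cycling: the data's rank order is
#' compared (Kendall's S) against cosine reference patterns over a grid of
#' periods and phase lags; each alternative gets an exact two-sided p-value
#' from the permutation null, the best alternative is the one maximizing
#' `|tau|` (ties broken by smaller p, then earlier lag), and the reported p
#' is Bonferroni-adjusted over the number of distinct alternatives tested.
#'
#' @param tc A `data.frame` with columns `ct` and `value` (and optionally
#'   `gene`, `replicate`), e.g. from [simulate_timecourse()], or a numeric
#'   vector of values with `timepoints` supplied.
#' @param timepoints Sample times when `tc` is a bare numeric vector.
#' @param periods_h Candidate periods (hours).
#' @param lag_step_h Phase-lag step (hours).
#' @param alpha Significance level for the `rhythmic` flag.
#' @return An object of class `jtk_result` with fields `gene`,
#'   `best_period_h`, `best_lag_h`, `tau`, `S`, `p_exact`, `p_adj`,
#'   `n_alternatives`, `rhythmic`.
#' @export
jtk_cycle <- function(tc, timepoints = NULL, periods_h = c(20, 24, 28),
                      lag_step_h = 4, alpha = 0.05) {
  if (is.numeric(tc)) {
    stopifnot(!is.null(timepoints), length(timepoints) == length(tc))
    tc <- data.frame(gene = "series", ct = timepoints, value = tc)
  }
  stopifnot(all(c("ct", "value") %in% names(tc)))
  gene <- if ("gene" %in% names(tc)) tc$gene[1] else "series"
  if (any(!is.finite(tc$value))) stop("values must be finite")
  tp <- sort(unique(tc$ct))
  patterns <- jtk_reference_patterns(tp, periods_h, lag_step_h)
  if (stats::var(tc$value) == 0) {
    res <- list(gene = gene, best_period_h = NA_real_, best_lag_h = NA_real_,
                tau = NA_real_, S = NA_real_, p_exact = 1, p_adj = 1,
                n_alternatives = length(patterns), rhythmic = FALSE,
                degenerate = TRUE)
    return(structure(res, class = "jtk_result"))
  }
  best <- NULL
  for (pat in patterns) {
    ref <- pat$ranks[match(tc$ct, tp)]
    ks <- kendall_s(tc$value, ref)
    if (is.na(ks$tau)) next
    p <- jtk_exact_p(ks$S, ref)
    cand <- list(period = pat$period_h, lag = pat$lag_h,
                 tau = ks$tau, S = ks$S, p = p)
    if (is.null(best) ||
        abs(cand$tau) > abs(best$tau) + 1e-12 ||
        (abs(abs(cand$tau) - abs(best$tau)) <= 1e-12 &&
         (cand$p < best$p - 1e-12 ||
          (abs(cand$p - best$p) <= 1e-12 && cand$lag < best$lag))))
      best <- cand
  }
  if (is.null(best))
    stop("degenerate time course: no testable alternative")
  p_adj <- min(1, best$p * length(patterns))
  structure(
    list(gene = gene, best_period_h = best$period, best_lag_h = best$lag,
         tau = best$tau, S = best$S, p_exact = best$p, p_adj = p_adj,
         n_alternatives = length(patterns), rhythmic = p_adj < alpha,
         degenerate = FALSE),
    class = "jtk_result")
}

#' @export
print.jtk_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("JTK %s: degenerate (constant values); not rhythmic\n",
                x$gene))
    return(invisible(x))
  }
  cat(sprintf(
    "JTK %s: %s (p_adj %.4g over %d alternatives); best period %g h, lag %g h, tau %.3f\n",
    x$gene, if (x$rhythmic) "rhythmic" else "not rhythmic",
    x$p_adj, x$n_alternatives, x$best_period_h, x$best_lag_h, x$tau))
  invisible(x)
}

#' Run JTK over a multi-gene tidy table
#'
#' @param df `data.frame` with columns `gene`, `ct`, `value`.
#' @param ... Passed to [jtk_cycle()].
#' @return A `data.frame`, one row per gene.
#' @export
jtk_table <- function(df, ...) {
  do.call(rbind, lapply(split(df, df$gene), function(d) {
    r <- jtk_cycle(d, ...)
    data.frame(gene = r$gene, best_period_h = r$best_period_h,
               best_lag_h = r$best_lag_h, tau = r$tau,
               p_exact = r$p_exact, p_adj = r$p_adj,
               rhythmic = r$rhythmic, stringsAsFactors = FALSE)
  }))
}
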