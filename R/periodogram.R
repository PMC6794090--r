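#' Lomb-Scargle periodogram of an activity series
#'
#' The floating-mean (least-squares) form of the normalized periodogram: at
#' each candidate period the power is the reduction in sum of squares from
#' fitting `x ~ 1 + cos(wt) + sin(wt)` divided by twice the sample variance,
#' so a pure sinusoid of period tau attains power `(N-1)/2` at tau and white
#' noise gives approximately Exp(1)-distributed power per period. The
#' significance line at level `alpha` uses the independent-frequency
#' approximation over the `M` candidate periods tested:
#' `-ln(1 - (1 - alpha)^(1/M))`, constant across periods.
#'
#' @param series An [activity_series()] with at least 2 days of uniformly
#'   binned data and non-zero variance.
#' @param period_range_h Candidate period range in hours.
#' @param alpha Significance level (the conventional circadian cutoff is
#'   0.001).
#' @param step_h Grid step in hours; defaults to the bin width, matching the
#'   chi-square grid for comparability.
#' @return An object of class `dam_periodogram`.
#' @export
ls_periodogram <- function(series, period_range_h = c(18, 30),
                           alpha = 0.001, step_h = NULL) {
  stopifnot(inherits(series, "activity_series"))
  x <- series$counts
  n <- length(x)
  if (n * series$bin_width < 2 * 1440)
    stop("need at least 2 days of data")
  if (stats::var(x) == 0) stop("constant signal: periodogram undefined")
  if (is.null(step_h)) step_h <- series$bin_width / 60
  periods <- period_grid(period_range_h, step_h)
  dt_h <- series$bin_width / 60
  t_h <- (seq_len(n) - 1) * dt_h
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  s2 <- ssx / (n - 1)
  stat <- vapply(periods, function(p) {
    w <- 2 * pi / p
    cv <- cos(w * t_h); sv <- sin(w * t_h)
    cv <- cv - mean(cv); sv <- sv - mean(sv)
    a <- sum(cv^2); b <- sum(cv * sv); d <- sum(sv^2)
    u <- sum(cv * xc); v <- sum(sv * xc)
    det <- a * d - b^2
    dss <- if (det > 1e-10 * max(a * d, 1)) {
      (d * u^2 - 2 * b * u * v + a * v^2) / det
    } else {
      # near-collinear regressors (e.g. period ~ 2N dt): 1-D projection
      if (a >= d) u^2 / a else v^2 / d
    }
    dss / (2 * s2)
  }, 1)
  thr <- -log(1 - (1 - alpha)^(1 / length(periods)))
  new_periodogram("lomb_scargle", periods, stat, rep(thr, length(periods)),
                  alpha, series$fly_id)
}

#' Chi-square (Sokolove-Bushell) periodogram of an activity series
#'
#' For each candidate period of `P` bins the series is folded into `P`
#' columns over the `K = floor(N/P)` complete cycles (a trailing partial
#' cycle is discarded) and
#' `Q_P = K * sum_h (M_h - Mbar)^2 / sigma2`, with column means `M_h`, grand
#' mean `Mbar` and variance `sigma2 = sum (x_i - Mbar)^2 / N'` over the `N'`
#' retained bins. Under the null `Q_P` is approximately chi-squared with
#' `P - 1` degrees of freedom, giving the per-period significance line at
#' level `alpha`. The peak height above the line is the conventional
#' "rhythm power" readout.
#'
#' @inheritParams ls_periodogram
#' @param period_range_h Candidate period range; the grid is every integer
#'   multiple of the bin width within it.
#' @return An object of class `dam_periodogram`.
#' @export
cs_periodogram <- function(series, period_range_h = c(18, 30),
                           alpha = 0.001) {
  stopifnot(inherits(series, "activity_series"))
  x <- series$counts
  n <- length(x)
  bw_h <- series$bin_width / 60
  periods <- period_grid(period_range_h, bw_h)
  p_bins <- as.integer(round(periods / bw_h))
  if (n < 2 * max(p_bins))
    stop(sprintf("need >= 2 complete cycles at the longest candidate period (%g h); have %.2f",
                 max(periods), n * bw_h / max(periods)))
  if (stats::var(x) == 0) stop("constant signal: periodogram undefined")
  stat <- vapply(p_bins, function(P) {
    K <- n %/% P
    np <- K * P
    xs <- x[seq_len(np)]
    mbar <- mean(xs)
    col_means <- rowsum(xs, rep_len(seq_len(P), np)) / K
    sig2 <- sum((xs - mbar)^2) / np
    K * sum((col_means - mbar)^2) / sig2
  }, 1)
  thr <- stats::qchisq(1 - alpha, df = p_bins - 1)
  new_periodogram("chi_square", periods, stat, thr, alpha, series$fly_id)
}

period_grid <- function(period_range_h, step_h) {
  stopifnot(length(period_range_h) == 2, period_range_h[1] > 0,
            period_range_h[2] >= period_range_h[1], step_h > 0)
  k <- seq(ceiling(period_range_h[1] / step_h - 1e-9),
           floor(period_range_h[2] / step_h + 1e-9))
  if (length(k) == 0) stop("empty candidate period grid")
  k * step_h
}

new_periodogram <- function(method, periods, stat, threshold, alpha,
                            fly_id) {
  i <- which.max(stat)
  structure(
    list(method = method, fly_id = fly_id,
         periods_h = periods, stat = stat, threshold = threshold,
         alpha = alpha,
         peak_period_h = periods[i], peak_stat = stat[i],
         peak_threshold = threshold[i]),
    class = "dam_periodogram")
}

#' @export
print.dam_periodogram <- function(x, ...) {
  cat(sprintf(
    "%s periodogram (%s): peak %.2f at %.2f h; threshold %.2f (alpha %g)\n",
    switch(x$method, lomb_scargle = "Lomb-Scargle", chi_square = "Chi-square"),
    x$fly_id, x$peak_stat, x$peak_period_h, x$peak_threshold, x$alpha))
  invisible(x)
}

#' @export
as.data.frame.dam_periodogram <- function(x, ...) {
  data.frame(period_h = x$periods_h, stat = x$stat, threshold = x$threshold)
}

#' @export
plot.dam_periodogram <- function(x, ...) {
  graphics::plot(x$periods_h, x$stat, type = "l",
                 xlab = "period (h)",
                 ylab = if (x$method == "chi_square") "Q_P" else "LS power",
                 ...)
  graphics::lines(x$periods_h, x$threshold, lty = 2)
  graphics::points(x$peak_period_h, x$peak_stat, pch = 19)
  invisible(x)
}
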