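#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()])
#' followed by Dunn's z-tests on mean ranks for every group pair:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`. Pairwise p-values are
#' multiplicity adjusted over all pairs (Bonferroni by default, the
#' convention for "multiplicity adjusted" Dunn reporting; Holm available).
#'
#' @param groups Named list of numeric vectors, or a `data.frame` with
#'   columns `group` and `value`. At least 2 groups of at least 2
#'   observations; `NA`s dropped listwise with a note in attribute `"log"`.
#' @param p_adjust `"bonferroni"` or `"holm"`.
#' @return An object of class `group_comparison`.
#' @export
kruskal_dunn <- function(groups, p_adjust = c("bonferroni", "holm")) {
  p_adjust <- match.arg(p_adjust)
  g <- as_group_list(groups)
  kw <- stats::kruskal.test(g$values, g$labels)
  x <- g$values
  f <- g$labels
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, f, mean)
  n <- tapply(r, f, length)
  ties <- table(x)
  tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(f)
  pairs <- utils::combn(lev, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tcorr) * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  new_group_comparison(
    method = "Kruskal-Wallis + Dunn",
    omnibus_stat = unname(kw$statistic), omnibus_p = kw$p.value,
    pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          stat = z, p_raw = p_raw, p_adj = p_adj,
                          stringsAsFactors = FALSE),
    log = g$log)
}

#' One-way ANOVA with Tukey's HSD post hoc comparisons
#'
#' @inheritParams kruskal_dunn
#' @return An object of class `group_comparison`; pairwise p-values are the
#'   studentized-range (Tukey) family-wise adjusted values.
#' @export
anova_tukey <- function(groups) {
  g <- as_group_list(groups)
  d <- data.frame(value = g$values, group = g$labels)
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pr <- strsplit(rownames(tk), "-", fixed = TRUE)
  new_group_comparison(
    method = "one-way ANOVA + Tukey HSD",
    omnibus_stat = s[["F value"]][1], omnibus_p = s[["Pr(>F)"]][1],
    pairwise = data.frame(group1 = vapply(pr, `[`, "", 2),
                          group2 = vapply(pr, `[`, "", 1),
                          stat = tk[, "diff"], p_raw = NA_real_,
                          p_adj = tk[, "p adj"],
                          stringsAsFactors = FALSE),
    log = g$log)
}

#' Advise parametric vs nonparametric testing
#'
#' Screens each group for normality (Shapiro-Wilk) and recommends the
#' nonparametric route if any group deviates at `alpha` or is too small to
#' screen. Advisory only: an explicit `override` (e.g. a per-figure analysis
#' choice) always wins.
#'
#' @param groups As in [kruskal_dunn()].
#' @param alpha Screening level.
#' @param override `"nonparametric"` or `"parametric"` to force the choice.
#' @return `"nonparametric"` or `"parametric"`.
#' @export
select_test <- function(groups, alpha = 0.05, override = NULL) {
  if (!is.null(override))
    return(match.arg(override, c("nonparametric", "parametric")))
  g <- as_group_list(groups)
  ps <- vapply(split(g$values, g$labels), function(v) {
    if (length(v) < 3 || length(v) > 5000 || stats::sd(v) == 0)
      return(0)  # unscreenable: fall back to the rank test
    stats::shapiro.test(v)$p.value
  }, 1)
  if (any(ps < alpha)) "nonparametric" else "parametric"
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    values <- groups$value
    labels <- groups$group
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    values <- unlist(groups, use.names = FALSE)
    labels <- rep(names(groups), lengths(groups))
  }
  log <- character(0)
  drop <- is.na(values)
  if (any(drop)) {
    log <- sprintf("dropped %d NA observation(s) before testing", sum(drop))
    values <- values[!drop]
    labels <- labels[!drop]
  }
  f <- factor(labels)
  n <- table(f)
  if (length(n) < 2) stop("need at least 2 groups")
  if (any(n < 2))
    stop("every group needs at least 2 observations; offending: ",
         paste(names(n)[n < 2], collapse = ", "))
  list(values = as.numeric(values), labels = f, log = log)
}

new_group_comparison <- function(method, omnibus_stat, omnibus_p, pairwise,
                                 log = character(0)) {
  structure(list(method = method, omnibus_stat = omnibus_stat,
                 omnibus_p = omnibus_p, pairwise = pairwise, log = log),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("%s: omnibus statistic %.*g, p = %.*g\n", x$method, digits,
              x$omnibus_stat, digits, x$omnibus_p))
  print(x$pairwise, digits = digits, row.names = FALSE)
  if (length(x$log)) cat(paste0("note: ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
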