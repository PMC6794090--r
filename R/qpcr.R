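#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 relative template amount over a
#' serial dilution series. The slope gives the primer amplification factor
#' `10^(-1/slope)` and efficiency `10^(-1/slope) - 1` (1.0 = 100%, i.e.
#' perfect doubling per cycle, slope -3.3219). Replicate Cts at a dilution
#' are averaged before regression by default.
#'
#' @param dilutions Relative template amounts (e.g. `1, 0.5, 0.25, ...`),
#'   > 0, at least 3 distinct values.
#' @param cts Corresponding Ct values (finite).
#' @param average_replicates Average replicate Cts per dilution before
#'   regressing (default) or regress on every well.
#' @return An object of class `standard_curve` with fields
#'   `log10_dilutions`, `ct_values`, `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `amplification_factor`.
#' @export
fit_standard_curve <- function(dilutions, cts, average_replicates = TRUE) {
  stopifnot(length(dilutions) == length(cts), all(dilutions > 0),
            all(is.finite(cts)))
  if (length(unique(dilutions)) < 3)
    stop("need at least 3 distinct dilutions")
  lx <- log10(dilutions)
  y <- cts
  if (average_replicates) {
    y <- tapply(cts, lx, mean)
    lx <- as.numeric(names(y))
    y <- as.numeric(y)
  }
  fit <- stats::lm(y ~ lx)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("non-amplifying curve: Ct does not decrease with template amount")
  structure(
    list(log10_dilutions = lx, ct_values = y,
         slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = 1 - sum(stats::residuals(fit)^2) /
           sum((y - mean(y))^2),
         efficiency = 10^(-1 / slope) - 1,
         amplification_factor = 10^(-1 / slope)),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: slope %.4f, intercept %.2f, R^2 %.4f\n  efficiency %.1f%% (amplification factor %.3f per cycle)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency,
    x$amplification_factor))
  invisible(x)
}

#' Relative template quantity from a Ct via a standard curve
#'
#' Inverts the fitted line: `quantity = 10^((ct - intercept) / slope)`, on
#' the same relative scale as the dilution series.
#'
#' @param ct Ct value(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Relative quantity, same length as `ct`.
#' @export
relative_quantity <- function(ct, curve) {
  if (!inherits(curve, "standard_curve"))
    stop("curve must be a fitted standard_curve")
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalize a target quantity to a reference gene
#'
#' Ratio of target to reference quantity (the reference-gene normalization
#' step; Actin5C is the conventional reference in fly head qPCR).
#'
#' @param target_qty,reference_qty Relative quantities (vectors recycled).
#' @return Relative expression level.
#' @export
normalize_to_reference <- function(target_qty, reference_qty) {
  if (any(reference_qty <= 0))
    stop("reference quantity must be positive")
  target_qty / reference_qty
}
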