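#' Construct an activity series
#'
#' One fly's binned beam-break counts with circadian phase and light-regime
#' annotation. Bins are half-open `[t, t + bin_width)` and timestamps are bin
#' starts. Phase labels are hours after (projected) lights-on, in `[0, 24)`:
#' ZT on LD days, CT on DD days. Day boundaries fall at phase 0.
#'
#' Most users will obtain series from [read_dam_monitor()] or
#' [simulate_fly()] rather than calling this constructor directly.
#'
#' @param fly_id Character identifier, unique within a cohort.
#' @param t0 `POSIXct` timestamp of the first bin start.
#' @param bin_width Bin width in minutes.
#' @param counts Non-negative integer beam-break counts, one per bin.
#' @param schedule A [light_schedule()] used to derive phase and regime
#'   labels. Ignored if `phase` and `regime` are supplied directly.
#' @param phase,regime Optional explicit per-bin labels (numeric hours in
#'   `[0, 24)` and `"LD"`/`"DD"`); normally derived from `schedule`.
#' @param flagged Optional logical vector marking bins read from
#'   invalid-status monitor rows (kept, as zero counts, to preserve regular
#'   sampling).
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(fly_id, t0, bin_width, counts, schedule = NULL,
                            phase = NULL, regime = NULL, flagged = NULL) {
  stopifnot(is.character(fly_id), length(fly_id) == 1,
            inherits(t0, "POSIXct"), length(t0) == 1,
            is.numeric(bin_width), length(bin_width) == 1, bin_width > 0)
  counts <- as.numeric(counts)
  n <- length(counts)
  if (n == 0) stop("counts must be non-empty")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(phase) || is.null(regime)) {
    if (is.null(schedule) || !inherits(schedule, "light_schedule"))
      stop("supply a light_schedule (or explicit phase and regime labels)")
    lab <- phase_labels(t0, bin_width, n, schedule)
    phase <- lab$phase
    regime <- lab$regime
  }
  if (length(phase) != n || length(regime) != n)
    stop("phase and regime labels must match counts in length")
  if (is.null(flagged)) flagged <- rep(FALSE, n)
  stopifnot(is.logical(flagged), length(flagged) == n)
  structure(
    list(fly_id = fly_id, t0 = t0, bin_width = bin_width,
         counts = counts, phase = phase, regime = regime, flagged = flagged),
    class = "activity_series")
}

# Phase (hours after lights-on, mod 24) and LD/DD regime per bin. Days are
# counted from the lights-on at or before t0; the first n_ld_days days are LD.
phase_labels <- function(t0, bin_width, n, schedule) {
  lt <- as.POSIXlt(t0, tz = "UTC")
  clock0 <- lt$hour + lt$min / 60 + lt$sec / 3600
  phase0 <- (clock0 - schedule$lights_on_hour) %% 24
  elapsed_h <- phase0 + (seq_len(n) - 1) * bin_width / 60
  phase <- elapsed_h %% 24
  day <- floor(elapsed_h / 24) + 1   # day 1 = first (possibly partial) day
  regime <- ifelse(day <= schedule$n_ld_days, "LD", "DD")
  list(phase = phase, regime = regime, day = day)
}

# Day number of each bin within its regime (LD day 1, ..., DD day 1, ...).
regime_day <- function(series) {
  elapsed_h <- series$phase[1] + (seq_along(series$counts) - 1) *
    series$bin_width / 60
  day <- floor(elapsed_h / 24) + 1
  out <- integer(length(day))
  for (r in unique(series$regime)) {
    i <- series$regime == r
    out[i] <- day[i] - min(day[i]) + 1L
  }
  out
}

#' @export
print.activity_series <- function(x, ...) {
  days <- length(x$counts) * x$bin_width / 1440
  cat(sprintf("Activity series '%s': %d x %g-min bins (%.2f days) from %s\n",
              x$fly_id, length(x$counts), x$bin_width,
              days, format(x$t0, "%Y-%m-%d %H:%M", tz = "UTC")))
  tab <- table(x$regime)
  cat(sprintf("  regime: %s; total %g beam breaks; %d flagged bin(s)\n",
              paste(sprintf("%s %d bins", names(tab), as.integer(tab)),
                    collapse = ", "),
              sum(x$counts), sum(x$flagged)))
  invisible(x)
}

#' @export
as.data.frame.activity_series <- function(x, ...) {
  data.frame(fly_id = x$fly_id,
             t = x$t0 + (seq_along(x$counts) - 1) * x$bin_width * 60,
             bin_width = x$bin_width,
             regime = x$regime,
             phase = x$phase,
             count = x$counts,
             flagged = x$flagged,
             stringsAsFactors = FALSE)
}

#' Re-bin an activity series to a coarser bin width
#'
#' Sums constituent bins, conserving total counts over complete bins; a
#' trailing partial bin is dropped with a message. Standard usage follows the
#' field's conventions: 15-min bins for periodogram analysis, 60-min bins for
#' anticipation indices.
#'
#' @param series An [activity_series()].
#' @param bin_width Target width in minutes; must be a multiple of the
#'   current width and divide 1440.
#' @return An [activity_series()] at the new bin width.
#' @export
bin_series <- function(series, bin_width) {
  stopifnot(inherits(series, "activity_series"))
  old <- series$bin_width
  if (bin_width %% old != 0)
    stop(sprintf("bin_width %g is not a multiple of current width %g",
                 bin_width, old))
  if (1440 %% bin_width != 0)
    stop("bin_width must divide 1440 minutes")
  k <- bin_width / old
  n <- length(series$counts)
  n_full <- floor(n / k)
  dropped <- n - n_full * k
  if (dropped > 0)
    message(sprintf("bin_series: dropped trailing partial bin (%d x %g-min bins)",
                    dropped, old))
  if (n_full == 0) stop("series shorter than one output bin")
  idx <- seq_len(n_full * k)
  grp <- rep(seq_len(n_full), each = k)
  counts <- as.numeric(rowsum(series$counts[idx], grp))
  first <- idx[seq(1, length(idx), by = k)]
  activity_series(series$fly_id, series$t0, bin_width, counts,
                  phase = series$phase[first],
                  regime = series$regime[first],
                  flagged = as.logical(rowsum(as.numeric(series$flagged[idx]),
                                              grp) > 0))
}

#' Extract whole circadian days from an activity series
#'
#' Returns exactly `n_days` complete days of the requested regime, starting
#' at the given day number within that regime (LD day 1 is the first LD day,
#' DD day 1 the first DD day). Windows begin at the day boundary (phase 0).
#'
#' @param series An [activity_series()].
#' @param regime `"LD"` or `"DD"`.
#' @param start_day First day of the window, counted within the regime.
#' @param n_days Number of whole days to return.
#' @return An [activity_series()] covering the window.
#' @export
slice_window <- function(series, regime = c("DD", "LD"), start_day = 1,
                         n_days = 1) {
  stopifnot(inherits(series, "activity_series"))
  regime <- match.arg(regime)
  day <- regime_day(series)
  in_reg <- series$regime == regime
  if (!any(in_reg)) stop(sprintf("series has no %s data", regime))
  avail <- max(day[in_reg])
  want <- in_reg & day >= start_day & day < start_day + n_days
  bins_per_day <- 1440 / series$bin_width
  expect <- n_days * bins_per_day
  if (sum(want) != expect || series$phase[which(want)[1]] != 0)
    stop(sprintf(
      "requested %s days %d-%d not fully available (%d complete-or-partial %s day(s) in record)",
      regime, start_day, start_day + n_days - 1, avail, regime))
  activity_series(series$fly_id,
                  series$t0 + (which(want)[1] - 1) * series$bin_width * 60,
                  series$bin_width, series$counts[want],
                  phase = series$phase[want], regime = series$regime[want],
                  flagged = series$flagged[want])
}
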