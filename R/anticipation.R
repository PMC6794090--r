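#' Morning or evening anticipation index
#'
#' The anticipation index is the sum of beam breaks in the 3 h immediately
#' preceding a light transition divided by the sum over the 6 h preceding
#' it, computed on hourly-binned activity. With transitions at phase 0
#' (lights-on, projected in DD) and phase 12 (lights-off), the morning index
#' (MAI) uses hours 21-23 over hours 18-23 and the evening index (EAI) uses
#' hours 9-11 over hours 6-11. Flat activity gives 0.5; values above 0.5
#' indicate anticipatory ramping. Equivalently a ratio of average hourly
#' activities, since both windows hold whole hourly bins.
#'
#' For multi-day spans, counts are summed across days before dividing
#' (robust to zero-activity days); set `per_day = TRUE` for the
#' mean-of-daily-indices alternative. A zero 6-h denominator yields `NA`
#' with attribute `undefined = TRUE`; such flies are excluded from group
#' statistics with a log entry.
#'
#' @param series An [activity_series()] at 60-min bins (see [bin_series()]).
#' @param transition `"lights_on"` (MAI) or `"lights_off"` (EAI).
#' @param regime `"LD"` or `"DD"` -- which part of the record the days refer
#'   to.
#' @param days Day numbers within the regime (e.g. `2` for day 2, `3:9` for
#'   a multi-day span).
#' @param per_day If `TRUE`, return the mean of per-day indices instead of
#'   the pooled ratio.
#' @return Numeric index in `[0, 1]`, or `NA` if undefined.
#' @export
anticipation_index <- function(series,
                               transition = c("lights_on", "lights_off"),
                               regime = "DD", days = 2, per_day = FALSE) {
  stopifnot(inherits(series, "activity_series"))
  transition <- match.arg(transition)
  if (series$bin_width != 60)
    stop("anticipation indices are defined on 60-min bins; use bin_series(series, 60)")
  win <- slice_window(series, regime, min(days), length(days))
  hours <- floor(win$phase)
  num_h <- if (transition == "lights_on") 21:23 else 9:11
  den_h <- if (transition == "lights_on") 18:23 else 6:11
  day_of <- rep(seq_along(days), each = 24)
  one <- function(sel) {
    num <- sum(win$counts[sel & hours %in% num_h])
    den <- sum(win$counts[sel & hours %in% den_h])
    if (den == 0) structure(NA_real_, undefined = TRUE) else num / den
  }
  if (per_day) {
    vals <- vapply(seq_along(days),
                   function(d) as.numeric(one(day_of == d)), 1)
    if (all(is.na(vals))) structure(NA_real_, undefined = TRUE)
    else mean(vals, na.rm = TRUE)
  } else {
    one(rep(TRUE, length(hours)))
  }
}

#' Anticipation indices for a cohort over named day spans
#'
#' Applies [anticipation_index()] per fly for each named span (the standard
#' spans are LD day 2, DD day 2, and DD days 3-9) and returns a tidy table
#' feeding the group-statistics module. Flies with an undefined index (zero
#' 6-h denominator) carry `NA` and are reported in the `log` attribute.
#'
#' @param cohort A list of [activity_series()] (any bin width dividing 60;
#'   binned internally) or a named list of such lists (groups).
#' @param spans Named list; each element is `list(regime =, days =)`.
#' @return A `data.frame` with columns `group`, `fly_id`, `span`, `mai`,
#'   `eai`, with exclusion messages in attribute `"log"`.
#' @export
cohort_anticipation <- function(cohort,
                                spans = list(
                                  LD2 = list(regime = "LD", days = 2),
                                  DD2 = list(regime = "DD", days = 2),
                                  `DD3-9` = list(regime = "DD", days = 3:9))) {
  if (inherits(cohort, "activity_series")) cohort <- list(cohort)
  grouped <- !inherits(cohort[[1]], "activity_series")
  groups <- if (grouped) cohort else list(cohort = cohort)
  log <- character(0)
  rows <- list()
  for (g in names(groups)) for (s in groups[[g]]) {
    sh <- if (s$bin_width == 60) s else bin_series(s, 60)
    for (sp in names(spans)) {
      mai <- anticipation_index(sh, "lights_on", spans[[sp]]$regime,
                                spans[[sp]]$days)
      eai <- anticipation_index(sh, "lights_off", spans[[sp]]$regime,
                                spans[[sp]]$days)
      if (is.na(mai) || is.na(eai))
        log <- c(log, sprintf(
          "%s %s: undefined index (zero 6-h denominator); excluded from group stats",
          s$fly_id, sp))
      rows[[length(rows) + 1]] <-
        data.frame(group = g, fly_id = s$fly_id, span = sp,
                   mai = as.numeric(mai), eai = as.numeric(eai),
                   stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), log = log)
}
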