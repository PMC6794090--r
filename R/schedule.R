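#' Define a light schedule for a DAM recording
#'
#' A light schedule anchors circadian phase labels: Zeitgeber time (ZT) during
#' entrained light:dark (LD) days and circadian time (CT) during constant
#' darkness (DD). ZT0 is lights-on; CT0 in DD is the projection of the prior
#' lights-on time, the only convention supported here. Days are counted from
#' the lights-on event at or before the first recorded sample; the first
#' `n_ld_days` days are labelled LD and all later days DD.
#'
#' @param lights_on_hour Clock hour of lights-on, in `[0, 24)`.
#' @param lights_off_hour Clock hour of lights-off, in `[0, 24)`. Must differ
#'   from `lights_on_hour`; the default pair gives the standard 12:12
#'   photoperiod.
#' @param n_ld_days Number of recorded LD days before release into DD
#'   (integer, >= 0).
#' @return An object of class `light_schedule`.
#' @examples
#' light_schedule(lights_on_hour = 8, lights_off_hour = 20, n_ld_days = 2)
#' @export
light_schedule <- function(lights_on_hour = 8, lights_off_hour = 20,
                           n_ld_days = 2) {
  stopifnot(is.numeric(lights_on_hour), length(lights_on_hour) == 1,
            is.numeric(lights_off_hour), length(lights_off_hour) == 1,
            is.numeric(n_ld_days), length(n_ld_days) == 1, n_ld_days >= 0)
  if (lights_on_hour < 0 || lights_on_hour >= 24 ||
      lights_off_hour < 0 || lights_off_hour >= 24)
    stop("clock hours must lie in [0, 24)")
  if (lights_on_hour == lights_off_hour)
    stop("lights_on_hour and lights_off_hour must differ")
  structure(
    list(lights_on_hour = lights_on_hour,
         lights_off_hour = lights_off_hour,
         photoperiod_h = (lights_off_hour - lights_on_hour) %% 24,
         n_ld_days = as.integer(n_ld_days)),
    class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf(
    "Light schedule: lights on %02.0f:00, off %02.0f:00 (%g:%g photoperiod), %d LD day(s) then DD\n",
    x$lights_on_hour, x$lights_off_hour, x$photoperiod_h,
    24 - x$photoperiod_h, x$n_ld_days))
  invisible(x)
}
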