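#' Parameters for one synthetic fly
#'
#' Describes the expected beam-break rate of a simulated fly as a bimodal
#' circadian template: a baseline rate modulated by raised-cosine morning and
#' evening activity peaks, optional linear anticipation ramps over the 3 h
#' preceding each (projected) light transition, and geometric day-by-day
#' damping. Counts are drawn per minute from a Poisson distribution (beam
#' breaks are sparse event counts); a negative-binomial dispersion knob is
#' available but off by default.
#'
#' The expected rate at elapsed time `t` (hours), on internal circadian phase
#' `phi = (phi0 + 24 t / period_h) mod 24`, is
#' `lambda(t) = baseline_rate * (1 + amplitude * (morning_weight *
#' bump_M(phi) + bump_E(phi)) + ramp(phi)) * (1 - damping_per_day)^day`,
#' with raised-cosine bumps of
#' half-width `peak_width_h` centred on the morning and evening peaks and a
#' linear ramp rising from 0 to `ramp_gain` over the 3 h before the
#' transition (phase 24 for morning, 12 for evening).
#'
#' @param period_h Free-running period tau in hours.
#' @param baseline_rate Expected counts per minute away from peaks (>= 0).
#' @param amplitude Multiplicative modulation of the peak template (>= 0).
#' @param morning_weight Relative height of the morning peak versus the
#'   evening peak, in `[0, 1]`. Free-running fly activity is
#'   evening-dominant; the default 0.5 keeps the profile bimodal while
#'   giving it the asymmetry (and hence the 24-h fundamental) real records
#'   show -- a perfectly symmetric pair of antiphase peaks would be a
#'   degenerate 12-h signal.
#' @param morning_peak_ct,evening_peak_ct Peak centres in circadian hours.
#' @param peak_width_h Raised-cosine half-width in hours.
#' @param anticipation_ramp Which transitions get an anticipation ramp.
#' @param ramp_gain Height of the ramp at the transition (>= 0).
#' @param damping_per_day Fractional decay of the whole rate per day,
#'   in `[0, 1)`.
#' @param arrhythmic If `TRUE`, all rhythm-bearing terms (amplitude and
#'   ramps) are forced to zero, leaving flat Poisson noise.
#' @param dispersion Negative-binomial size parameter; `Inf` (default) gives
#'   pure Poisson counts.
#' @param seed Integer seed making the fly reproducible.
#' @return An object of class `fly_params`.
#' @export
fly_params <- function(period_h = 24, baseline_rate = 1, amplitude = 2,
                       morning_weight = 0.5,
                       morning_peak_ct = 0, evening_peak_ct = 12,
                       peak_width_h = 3,
                       anticipation_ramp = c("none", "morning", "evening",
                                             "both"),
                       ramp_gain = 1, damping_per_day = 0,
                       arrhythmic = FALSE, dispersion = Inf, seed = 1) {
  anticipation_ramp <- match.arg(anticipation_ramp)
  stopifnot(period_h > 0, baseline_rate >= 0, amplitude >= 0,
            morning_weight >= 0, morning_weight <= 1,
            peak_width_h > 0, ramp_gain >= 0,
            damping_per_day >= 0, damping_per_day < 1, dispersion > 0)
  if (arrhythmic) {
    amplitude <- 0
    ramp_gain <- 0
    anticipation_ramp <- "none"
  }
  structure(
    list(period_h = period_h, baseline_rate = baseline_rate,
         amplitude = amplitude, morning_weight = morning_weight,
         morning_peak_ct = morning_peak_ct %% 24,
         evening_peak_ct = evening_peak_ct %% 24,
         peak_width_h = peak_width_h,
         anticipation_ramp = anticipation_ramp, ramp_gain = ramp_gain,
         damping_per_day = damping_per_day, arrhythmic = arrhythmic,
         dispersion = dispersion, seed = as.integer(seed)),
    class = "fly_params")
}

# Raised-cosine bump of half-width w centred at c, on circular phase (h).
.bump <- function(phi, centre, w) {
  d <- abs((phi - centre + 12) %% 24 - 12)
  ifelse(d < w, 0.5 * (1 + cos(pi * d / w)), 0)
}

# Linear anticipation ramp rising over the 3 h before `transition` phase.
.ramp <- function(phi, transition, gain) {
  d <- (transition - phi) %% 24   # hours until transition
  ifelse(d > 0 & d <= 3, gain * (3 - d) / 3, 0)
}

#' Expected beam-break rate of a synthetic fly
#'
#' @param params A [fly_params()].
#' @param t_h Elapsed hours since recording start (phase 0).
#' @param phase0 Internal circadian phase at `t_h = 0`.
#' @return Expected counts per minute at each `t_h`.
#' @export
expected_rate <- function(params, t_h, phase0 = 0) {
  phi <- (phase0 + t_h * 24 / params$period_h) %% 24
  mod <- 1 + params$amplitude *
    (params$morning_weight *
       .bump(phi, params$morning_peak_ct, params$peak_width_h) +
     .bump(phi, params$evening_peak_ct, params$peak_width_h))
  if (params$anticipation_ramp %in% c("morning", "both"))
    mod <- mod + .ramp(phi, 24, params$ramp_gain)
  if (params$anticipation_ramp %in% c("evening", "both"))
    mod <- mod + .ramp(phi, 12, params$ramp_gain)
  day <- floor(t_h / 24)
  lam <- params$baseline_rate * mod *
    (1 - params$damping_per_day)^day
  if (any(lam < 0)) stop("negative expected rate; check parameters")
  lam
}

#' Simulate one fly's DAM recording
#'
#' Draws per-minute counts from the counting model in [fly_params()] across
#' `n_ld_days` entrained days followed by `n_dd_days` of constant darkness.
#' The recording starts at lights-on (phase 0) of the first day.
#'
#' @param params A [fly_params()].
#' @param schedule A [light_schedule()]; its `n_ld_days` is overridden by
#'   `n_ld_days` here so the labels match the simulated protocol.
#' @param n_ld_days,n_dd_days Days of LD and DD to simulate.
#' @param phase0 Internal circadian phase at recording start (hours); the
#'   phase *labels* always start at 0 (lights-on).
#' @param t0 Recording start timestamp; defaults to lights-on on an
#'   arbitrary fixed date.
#' @return An [activity_series()] at 1-min bins.
#' @export
simulate_fly <- function(params, schedule = light_schedule(),
                         n_ld_days = 2, n_dd_days = 9, phase0 = 0,
                         t0 = NULL) {
  stopifnot(inherits(params, "fly_params"), n_ld_days >= 0, n_dd_days >= 0,
            n_ld_days + n_dd_days > 0)
  schedule <- light_schedule(schedule$lights_on_hour,
                             schedule$lights_off_hour, n_ld_days)
  if (is.null(t0))
    t0 <- as.POSIXct(sprintf("2024-01-01 %02d:00:00",
                             round(schedule$lights_on_hour)), tz = "UTC")
  n_min <- (n_ld_days + n_dd_days) * 1440L
  t_h <- (seq_len(n_min) - 1) / 60
  lam <- expected_rate(params, t_h, phase0)
  counts <- with_seed(params$seed, {
    if (is.finite(params$dispersion))
      stats::rnbinom(n_min, size = params$dispersion,
                     mu = lam)
    else stats::rpois(n_min, lam)
  })
  activity_series(sprintf("sim%08d", params$seed), t0, 1, counts,
                  schedule = schedule)
}

#' Specify a synthetic cohort
#'
#' A cohort of flies sharing template parameters, with per-fly Gaussian
#' jitter on period and starting phase. Each fly's seed is derived
#' deterministically from `master_seed` and its index, so results do not
#' depend on cohort size ordering.
#'
#' @param n_flies Number of flies (> 0).
#' @param params Shared [fly_params()] template.
#' @param period_jitter_sd,phase_jitter_sd Per-fly SD of period (h) and
#'   starting internal phase (h).
#' @param n_ld_days,n_dd_days Protocol lengths in days.
#' @param master_seed Integer master seed.
#' @param label Group label attached to the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_flies = 32, params = fly_params(),
                        period_jitter_sd = 0.2, phase_jitter_sd = 0.5,
                        n_ld_days = 2, n_dd_days = 9, master_seed = 1,
                        label = "group") {
  if (n_flies <= 0) stop("n_flies must be positive")
  stopifnot(inherits(params, "fly_params"),
            period_jitter_sd >= 0, phase_jitter_sd >= 0)
  structure(
    list(n_flies = as.integer(n_flies), params = params,
         period_jitter_sd = period_jitter_sd,
         phase_jitter_sd = phase_jitter_sd,
         n_ld_days = n_ld_days, n_dd_days = n_dd_days,
         master_seed = as.integer(master_seed), label = label),
    class = "cohort_spec")
}

#' Simulate a cohort of flies
#'
#' @param spec A [cohort_spec()].
#' @param schedule A [light_schedule()].
#' @return A named list of [activity_series()] (class `cohort`), one per fly.
#' @export
simulate_cohort <- function(spec, schedule = light_schedule()) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", spec$n_flies)
  for (i in seq_len(spec$n_flies)) {
    fs <- derive_seed(spec$master_seed, i)
    jit <- with_seed(derive_seed(spec$master_seed, i, salt = 77L),
                     stats::rnorm(2))
    p <- spec$params
    p$period_h <- p$period_h + jit[1] * spec$period_jitter_sd
    p$seed <- fs
    s <- simulate_fly(p, schedule, spec$n_ld_days, spec$n_dd_days,
                      phase0 = (jit[2] * spec$phase_jitter_sd) %% 24)
    s$fly_id <- sprintf("%s#%02d", spec$label, i)
    out[[i]] <- s
  }
  names(out) <- vapply(out, function(s) s$fly_id, "")
  structure(out, class = "cohort", label = spec$label)
}

#' Simulate a qPCR-style expression time course
#'
#' Cosine mean with multiplicative lognormal noise:
#' `y = mesor * (1 + rel_amplitude * cos(2 pi (t - acrophase_ct) / period_h))
#' * eps`, where `eps` is lognormal with mean 1 and coefficient of variation
#' `noise_cv`. `rel_amplitude = 0` defines the arrhythmic null.
#'
#' @param mesor Positive mean level.
#' @param rel_amplitude Relative amplitude in `[0, 1]`.
#' @param period_h Period in hours.
#' @param acrophase_ct Peak time in circadian hours.
#' @param noise_cv Lognormal coefficient of variation (>= 0).
#' @param timepoints Sampled circadian times (hours); the default is the
#'   7-point design CT 1, 5, ..., 25 (CT1 and CT25 are distinct samples one
#'   cycle apart).
#' @param n_replicates Replicates per timepoint.
#' @param gene Gene label.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `gene`, `ct`, `replicate`, `value`.
#' @export
simulate_timecourse <- function(mesor = 1, rel_amplitude = 0.5,
                                period_h = 24, acrophase_ct = 0,
                                noise_cv = 0.2,
                                timepoints = c(1, 5, 9, 13, 17, 21, 25),
                                n_replicates = 4, gene = "gene", seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  stopifnot(mesor > 0, rel_amplitude >= 0, rel_amplitude <= 1, period_h > 0,
            n_replicates >= 1)
  ct <- rep(timepoints, each = n_replicates)
  mu <- mesor * (1 + rel_amplitude * cos(2 * pi * (ct - acrophase_ct) /
                                           period_h))
  eps <- if (noise_cv == 0) rep(1, length(ct)) else {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_seed(seed, stats::rlnorm(length(ct), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog))
  }
  data.frame(gene = gene, ct = ct,
             replicate = rep(seq_len(n_replicates), times = length(timepoints)),
             value = mu * eps, stringsAsFactors = FALSE)
}

#' Simulate a nucleus image with ground-truth masks
#'
#' Places disjoint disk-shaped nuclei of specified mean foreground intensity
#' on a uniform background, adds Gaussian noise, and returns both the image
#' and the integer label mask. A stand-in for confocal sections with
#' hand-identified nuclei; it makes no attempt at realistic optics.
#'
#' @param n_nuclei Number of nuclei.
#' @param intensities Mean foreground intensity per nucleus (recycled).
#' @param background_level Uniform background intensity.
#' @param noise_sd Gaussian pixel noise SD.
#' @param radius Disk radius in pixels.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param seed Integer seed.
#' @return A list with `image` (numeric matrix) and `masks` (integer label
#'   matrix, 0 = background, k = nucleus k).
#' @export
simulate_nucleus_image <- function(n_nuclei = 16, intensities = 100,
                                   background_level = 20, noise_sd = 0,
                                   radius = 4, dim = c(128, 128), seed = 1) {
  stopifnot(n_nuclei >= 1, noise_sd >= 0, radius >= 1)
  intensities <- rep_len(intensities, n_nuclei)
  masks <- matrix(0L, dim[1], dim[2])
  centres <- with_seed(seed, {
    placed <- matrix(NA_real_, n_nuclei, 2)
    tries <- 0
    k <- 1
    while (k <= n_nuclei) {
      if (tries > 200 * n_nuclei)
        stop("cannot place ", n_nuclei,
             " non-overlapping nuclei at this density")
      cand <- c(stats::runif(1, radius + 1, dim[1] - radius),
                stats::runif(1, radius + 1, dim[2] - radius))
      tries <- tries + 1
      if (k == 1 || all(sqrt(rowSums(sweep(placed[seq_len(k - 1), ,
                                                  drop = FALSE],
                                           2, cand)^2)) > 2 * radius + 2)) {
        placed[k, ] <- cand
        k <- k + 1
      }
    }
    placed
  })
  rr <- row(masks); cc <- col(masks)
  img <- matrix(background_level, dim[1], dim[2])
  for (k in seq_len(n_nuclei)) {
    inside <- (rr - centres[k, 1])^2 + (cc - centres[k, 2])^2 <= radius^2
    masks[inside] <- k
    img[inside] <- intensities[k]
  }
  if (noise_sd > 0)
    img <- img + with_seed(derive_seed(seed, 2L),
                           stats::rnorm(length(img), 0, noise_sd))
  list(image = img, masks = masks)
}
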