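#' Double-plotted actogram matrix
#'
#' Row `d` of a double-plotted actogram is the concatenation of day `d` and
#' day `d + 1` activity, so the right half of each row equals the left half
#' of the next. For a group, activity is averaged across flies per bin.
#'
#' @param x An [activity_series()] or a list of them (a group).
#' @param n_days Number of double-plotted rows; needs `n_days + 1` days of
#'   data.
#' @param regime `"DD"` or `"LD"`: which part of the record to plot.
#' @param start_day First day within the regime.
#' @param bin_width Bin width in minutes for the plotted matrix.
#' @return A numeric matrix (`n_days` rows, `2 * 1440 / bin_width` columns)
#'   of class `actogram_matrix`.
#' @export
actogram_matrix <- function(x, n_days = 6, regime = "DD", start_day = 1,
                            bin_width = 30) {
  if (inherits(x, "activity_series")) x <- list(x)
  stopifnot(length(x) >= 1, n_days >= 1)
  per_day <- 1440 / bin_width
  mats <- lapply(x, function(s) {
    win <- slice_window(s, regime, start_day, n_days + 1)
    if (win$bin_width != bin_width) win <- bin_series(win, bin_width)
    v <- win$counts
    t(vapply(seq_len(n_days), function(d)
      v[((d - 1) * per_day + 1):((d + 1) * per_day)],
      numeric(2 * per_day)))
  })
  out <- Reduce(`+`, mats) / length(mats)
  structure(out, class = c("actogram_matrix", "matrix"),
            bin_width = bin_width, regime = regime)
}

#' Assemble and validate a pipeline run configuration
#'
#' Fills the conventional defaults for the full locomotor analysis:
#' periodogram level `alpha = 0.001` over 18-30 h, rhythmicity cutoff 150
#' (or `"calibrate"` to set it from a simulated null cohort), 15-min bins
#' for periodograms, anticipation spans LD day 2 / DD day 2 / DD days 3-9,
#' and a 2-day LD + 9-day DD synthetic protocol. Validation is idempotent:
#' re-validating a validated config is a no-op.
#'
#' @param groups Named list describing synthetic groups; each element is a
#'   list of [fly_params()] overrides (e.g. `list(arrhythmic = TRUE)`),
#'   plus optional `n_flies`. Ignored in DAM-file mode.
#' @param dam_files Optional named list for file mode: each element
#'   `list(path =, channels =, genotype =)`.
#' @param schedule A [light_schedule()].
#' @param alpha,delta_threshold,period_range_h Rhythmicity settings (see
#'   [rhythm_config()]); `delta_threshold = "calibrate"` triggers null
#'   calibration at run time.
#' @param n_flies,n_ld_days,n_dd_days Synthetic cohort protocol.
#' @param dd_window Days of DD used for classification (start, length).
#' @param spans Anticipation spans, as in [cohort_anticipation()].
#' @param master_seed Integer master seed; every random draw in the run
#'   derives from it.
#' @return A validated config of class `run_config`.
#' @export
run_config <- function(groups = list(
                         control = list(arrhythmic = FALSE),
                         clockless = list(arrhythmic = TRUE)),
                       dam_files = NULL,
                       schedule = light_schedule(),
                       alpha = 0.001, delta_threshold = "calibrate",
                       period_range_h = c(18, 30),
                       n_flies = 16, n_ld_days = 2, n_dd_days = 9,
                       dd_window = c(1, 9),
                       spans = list(
                         DD2 = list(regime = "DD", days = 2),
                         `DD3-9` = list(regime = "DD", days = 3:9)),
                       master_seed = 1) {
  cfg <- list(groups = groups, dam_files = dam_files, schedule = schedule,
              alpha = alpha, delta_threshold = delta_threshold,
              period_range_h = period_range_h, n_flies = n_flies,
              n_ld_days = n_ld_days, n_dd_days = n_dd_days,
              dd_window = dd_window, spans = spans,
              master_seed = master_seed)
  validate_config(cfg)
}

#' @rdname run_config
#' @param config A (possibly partial) config list.
#' @export
validate_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  defaults <- list(groups = list(control = list(arrhythmic = FALSE),
                                 clockless = list(arrhythmic = TRUE)),
                   dam_files = NULL, schedule = light_schedule(),
                   alpha = 0.001, delta_threshold = 150,
                   period_range_h = c(18, 30), n_flies = 16,
                   n_ld_days = 2, n_dd_days = 9, dd_window = c(1, 9),
                   spans = list(DD2 = list(regime = "DD", days = 2),
                                `DD3-9` = list(regime = "DD", days = 3:9)),
                   master_seed = 1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(config))        # replace wholesale; never merge nested
    if (!is.null(config[[nm]])) cfg[[nm]] <- config[[nm]]
  if (!inherits(cfg$schedule, "light_schedule"))
    stop("schedule must be a light_schedule")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!(identical(cfg$delta_threshold, "calibrate") ||
        (is.numeric(cfg$delta_threshold) &&
         length(cfg$delta_threshold) == 1)))
    stop("delta_threshold must be a number or \"calibrate\"")
  if (cfg$dd_window[1] < 1 ||
      cfg$dd_window[1] + cfg$dd_window[2] - 1 > cfg$n_dd_days)
    stop("dd_window exceeds the DD record")
  for (sp in cfg$spans) {
    if (!sp$regime %in% c("LD", "DD")) stop("span regime must be LD or DD")
    lim <- if (sp$regime == "LD") cfg$n_ld_days else cfg$n_dd_days
    if (max(sp$days) > lim)
      stop(sprintf("span days %s exceed the %d recorded %s day(s)",
                   paste(range(sp$days), collapse = "-"), lim, sp$regime))
  }
  structure(cfg, class = "run_config")
}

#' Run the full locomotor analysis pipeline
#'
#' Simulates (or reads) a cohort per group, classifies every fly
#' (periodograms, rhythmic/arrhythmic call, period, rhythm power), computes
#' anticipation indices over the configured spans, runs the group
#' statistics (Kruskal-Wallis + Dunn on MAI and on rhythm power), builds
#' double-plotted actogram matrices, and writes everything as TSV plus a
#' provenance JSON capturing seeds and thresholds. Deterministic given the
#' master seed: reruns are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing). `NULL` returns
#'   results without writing.
#' @return Invisibly, a list with `calls`, `summary`, `anticipation`,
#'   `stats`, `actograms`, `provenance`, `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  config <- validate_config(config)
  cohorts <- pipeline_cohorts(config)
  thr <- config$delta_threshold
  if (identical(thr, "calibrate"))
    thr <- as.numeric(calibrate_delta_threshold(
      n_flies = 200, n_dd_days = config$dd_window[2],
      alpha = config$alpha, period_range_h = config$period_range_h,
      seed = derive_seed(config$master_seed, 999L)))
  rcfg <- rhythm_config(delta_threshold = thr, alpha = config$alpha,
                        period_range_h = config$period_range_h,
                        min_days = min(7, config$dd_window[2]))
  log <- character(0)
  calls <- list()
  summaries <- list()
  for (g in names(cohorts)) {
    gc <- lapply(cohorts[[g]], function(s) {
      win <- tryCatch(
        bin_series(slice_window(s, "DD", config$dd_window[1],
                                config$dd_window[2]), 15),
        error = function(e) stop(sprintf("stage rhythmicity, fly %s: %s",
                                         s$fly_id, conditionMessage(e))))
      classify_fly(win, rcfg)
    })
    calls[[g]] <- gc
    summaries[[g]] <- summarize_cohort(gc, label = g)
  }
  call_df <- do.call(rbind, lapply(names(calls), function(g)
    cbind(group = g, rhythm_call_table(calls[[g]]))))
  summary_df <- do.call(rbind, summaries)
  antic <- cohort_anticipation(cohorts, spans = config$spans)
  log <- c(log, attr(antic, "log"))

  stats_out <- list()
  first_span <- names(config$spans)[1]
  amai <- antic[antic$span == first_span & !is.na(antic$mai), ]
  if (length(unique(amai$group)) >= 2 && all(table(amai$group) >= 2))
    stats_out$mai <- kruskal_dunn(data.frame(group = amai$group,
                                             value = amai$mai))
  pw <- data.frame(group = call_df$group, value = call_df$cs_power_reported)
  if (length(unique(pw$group)) >= 2 && all(table(pw$group) >= 2))
    stats_out$rhythm_power <- kruskal_dunn(pw)

  act_days <- min(6, config$dd_window[2] - 1)
  actograms <- lapply(cohorts, actogram_matrix, n_days = act_days,
                      regime = "DD", start_day = config$dd_window[1])

  provenance <- list(
    package = "circadam",
    version = as.character(utils::packageVersion("circadam")),
    master_seed = config$master_seed,
    alpha = config$alpha,
    delta_threshold = thr,
    delta_threshold_mode = if (identical(config$delta_threshold,
                                         "calibrate"))
      "null-calibrated" else "fixed",
    period_range_h = config$period_range_h,
    dd_window = config$dd_window,
    spans = lapply(config$spans, function(s)
      list(regime = s$regime, days = range(s$days))),
    groups = lapply(cohorts, length))

  res <- list(calls = call_df, summary = summary_df, anticipation = antic,
              stats = stats_out, actograms = actograms,
              provenance = provenance, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

pipeline_cohorts <- function(config) {
  if (!is.null(config$dam_files)) {
    cohorts <- list()
    for (nm in names(config$dam_files)) {
      f <- config$dam_files[[nm]]
      if (is.null(f$genotype))
        stop("no genotype map entry for DAM input '", nm, "'")
      series <- read_dam_monitor(f$path, config$schedule,
                                 channels = f$channels, monitor = nm)
      cohorts[[f$genotype]] <- c(cohorts[[f$genotype]], series)
    }
    return(cohorts)
  }
  cohorts <- list()
  for (i in seq_along(config$groups)) {
    g <- names(config$groups)[i]
    ov <- config$groups[[i]]
    n <- ov$n_flies %||% config$n_flies
    ov$n_flies <- NULL
    params <- do.call(fly_params, ov)
    spec <- cohort_spec(n_flies = n, params = params,
                        n_ld_days = config$n_ld_days,
                        n_dd_days = config$n_dd_days,
                        master_seed = derive_seed(config$master_seed, i),
                        label = g)
    cohorts[[g]] <- simulate_cohort(spec, config$schedule)
  }
  cohorts
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(res$calls, "rhythm_calls.tsv")
  tsv(res$summary, "cohort_summary.tsv")
  tsv(res$anticipation, "anticipation.tsv")
  for (nm in names(res$stats))
    tsv(res$stats[[nm]]$pairwise, sprintf("stats_%s_pairwise.tsv", nm))
  for (nm in names(res$actograms))
    utils::write.table(unclass(res$actograms[[nm]]),
                       file.path(out_dir, sprintf("actogram_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  jsonlite::write_json(res$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
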