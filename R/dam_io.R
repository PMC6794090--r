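#' Read a TriKinetics DAM monitor file
#'
#' Parses the classic Monitor*.txt dialect: one tab-delimited row per minute
#' with a reading index, date (`dd-mmm-yy`), time (`HH:MM:SS`), a status code,
#' six further metadata columns, then 32 channel count columns (42 columns in
#' all). Other layouts are rejected rather than guessed at. Rows with a
#' status code other than 1 are kept with zero counts and flagged, so the
#' sampling stays regular (the periodograms assume even spacing).
#'
#' @param path Path to a monitor file.
#' @param schedule A [light_schedule()] used to annotate phase and regime.
#' @param channels Integer channel numbers (1-32) to return; default all
#'   channels with at least one beam break.
#' @param monitor Monitor name used to build fly ids (`"<monitor>#<ch>"`);
#'   defaults to the file name without extension.
#' @return A list of [activity_series()] at 1-min bins, one per channel.
#' @export
read_dam_monitor <- function(path, schedule, channels = NULL,
                             monitor = NULL) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (is.null(monitor))
    monitor <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty monitor file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 42L)
  if (length(bad) > 0)
    stop(sprintf("malformed DAM row at line %d of %s: %d columns (expected 42)",
                 bad[1], path, nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = 42L, byrow = TRUE)
  tt <- parse_dam_time(m[, 2], m[, 3], path)
  if (any(diff(as.numeric(tt)) <= 0))
    stop("non-monotonic timestamps in ", path)
  status <- suppressWarnings(as.integer(m[, 4]))
  counts <- matrix(suppressWarnings(as.numeric(m[, 11:42])), ncol = 32L)
  if (any(is.na(counts)))
    stop("non-numeric count field in ", path)
  flag <- is.na(status) | status != 1L
  counts[flag, ] <- 0
  if (is.null(channels)) channels <- which(colSums(counts) > 0)
  lapply(channels, function(ch) {
    activity_series(sprintf("%s#%02d", monitor, ch), tt[1], 1,
                    counts[, ch], schedule = schedule,
                    flagged = flag)
  })
}

.dam_months <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                 "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# Locale-independent parse of "dd-mmm-yy" + "HH:MM:SS" into UTC POSIXct.
parse_dam_time <- function(date, time, path) {
  d <- strsplit(date, "-", fixed = TRUE)
  if (any(lengths(d) != 3)) stop("malformed date field in ", path)
  d <- matrix(unlist(d), ncol = 3, byrow = TRUE)
  mon <- match(d[, 2], .dam_months)
  if (any(is.na(mon))) stop("unrecognized month abbreviation in ", path)
  iso <- sprintf("20%s-%02d-%s %s", d[, 3], mon, d[, 1], time)
  tt <- as.POSIXct(iso, tz = "UTC")
  if (any(is.na(tt))) stop("malformed timestamp in ", path)
  tt
}

#' Write activity series as a TriKinetics DAM monitor file
#'
#' Inverse of [read_dam_monitor()]: emits the 42-column Monitor*.txt layout.
#' Series are placed in channels 1..n and remaining channels padded with
#' zeros. Intended mainly for generating round-trippable fixtures from
#' simulated cohorts.
#'
#' @param series A list of [activity_series()] (at most 32), all at 1-min
#'   bins, equal length, sharing `t0`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(series, path) {
  if (inherits(series, "activity_series")) series <- list(series)
  if (length(series) > 32) stop("a DAM monitor has 32 channels; got ",
                                length(series), " series")
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, TRUE, "activity_series")))
  n <- length(series[[1]]$counts)
  if (any(vapply(series, function(s) length(s$counts), 1L) != n))
    stop("all series must have equal length")
  if (any(vapply(series, function(s) s$bin_width, 1) != 1))
    stop("DAM monitor files hold 1-min bins; rebin or simulate at 1 min")
  tt <- as.POSIXlt(series[[1]]$t0 + (seq_len(n) - 1) * 60, tz = "UTC")
  counts <- matrix(0, nrow = n, ncol = 32)
  for (i in seq_along(series)) counts[, i] <- series[[i]]$counts
  rows <- paste(
    seq_len(n),
    sprintf("%02d-%s-%02d", tt$mday, .dam_months[tt$mon + 1],
            tt$year %% 100),
    sprintf("%02d:%02d:%02d", tt$hour, tt$min, floor(tt$sec)),
    1,  # status: valid reading
    1, 0, 0, 0, 0, 0,
    apply(counts, 1, paste, collapse = "\t"),
    sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Export activity series as a tidy table
#'
#' Long-format table (`fly_id`, `t`, `bin_width`, `regime`, `phase`,
#' `count`, `flagged`), the package's interchange format for binned
#' activity.
#'
#' @param series An [activity_series()] or list of them.
#' @param path Optional TSV path; if supplied the table is also written.
#' @return A `data.frame`, invisibly if `path` is given.
#' @export
activity_table <- function(series, path = NULL) {
  if (inherits(series, "activity_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  if (!is.null(path)) {
    out <- df
    out$t <- format(out$t, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
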