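#' Measure background-subtracted nuclear fluorescence
#'
#' For each labeled nucleus mask, the mean pixel intensity minus the mean
#' over a background region: `net = mean(mask pixels) - mean(background)`.
#' Net intensities may be negative and are retained raw (floor them only in
#' display tables), keeping downstream statistics honest. Segmentation is
#' out of scope: masks are inputs, e.g. hand-identified nuclei or the
#' ground-truth masks from [simulate_nucleus_image()].
#'
#' @param image Numeric matrix of pixel intensities (arbitrary units).
#' @param masks Integer label matrix, same dimensions; 0 = unlabeled,
#'   k = nucleus k. Labels must be disjoint by construction.
#' @param background_roi Logical matrix selecting background pixels; must
#'   not overlap any mask. Default: all unlabeled pixels.
#' @param brain_id Identifier attached to the measurements.
#' @param cell_class Optional per-nucleus class labels (recycled).
#' @return A `data.frame` with one row per nucleus: `brain_id`, `cell_id`,
#'   `cell_class`, `mean_intensity`, `background_mean`, `net_intensity`.
#' @export
measure_nuclei <- function(image, masks, background_roi = NULL,
                           brain_id = "brain", cell_class = NA_character_) {
  stopifnot(is.matrix(image), is.matrix(masks),
            all(dim(image) == dim(masks)))
  labels <- sort(unique(masks[masks > 0]))
  if (length(labels) == 0) stop("no labeled nuclei in mask")
  if (is.null(background_roi)) {
    background_roi <- masks == 0
  } else {
    stopifnot(is.logical(background_roi),
              all(dim(background_roi) == dim(image)))
    if (any(background_roi & masks > 0))
      stop("background ROI overlaps a nucleus mask")
  }
  if (!any(background_roi)) stop("empty background ROI")
  bg <- mean(image[background_roi])
  cell_class <- rep_len(cell_class, length(labels))
  means <- vapply(labels, function(k) {
    px <- image[masks == k]
    if (length(px) == 0) stop("empty mask for label ", k)
    mean(px)
  }, 1)
  data.frame(brain_id = brain_id, cell_id = labels,
             cell_class = cell_class, mean_intensity = means,
             background_mean = bg, net_intensity = means - bg,
             stringsAsFactors = FALSE)
}

#' Count marker-positive cells per brain
#'
#' Counts nuclei whose background-subtracted intensity exceeds a threshold
#' (e.g. GFP-positive neurons per brain).
#'
#' @param measurements A [measure_nuclei()] table (possibly several brains
#'   row-bound together).
#' @param threshold Net-intensity cutoff (>= 0).
#' @return A `data.frame` per brain: `brain_id`, `n_cells`,
#'   `n_positive`.
#' @export
count_positive_cells <- function(measurements, threshold = 0) {
  if (threshold < 0) stop("threshold must be non-negative")
  stopifnot(is.data.frame(measurements),
            all(c("brain_id", "net_intensity") %in% names(measurements)))
  do.call(rbind, lapply(split(measurements, measurements$brain_id),
                        function(d) data.frame(
                          brain_id = d$brain_id[1],
                          n_cells = nrow(d),
                          n_positive = sum(d$net_intensity > threshold),
                          stringsAsFactors = FALSE)))
}

#' Per-brain mean nuclear intensity
#'
#' Unweighted mean of net intensities per brain. Brains, not nuclei, are the
#' statistical unit passed to group comparisons. Brains with no measured
#' nuclei are simply absent (excluded upstream with a log entry).
#'
#' @param measurements A [measure_nuclei()] table.
#' @return A `data.frame` per brain: `brain_id`, `n_cells`,
#'   `mean_net_intensity`.
#' @export
per_brain_mean <- function(measurements) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1,
            all(c("brain_id", "net_intensity") %in% names(measurements)))
  do.call(rbind, lapply(split(measurements, measurements$brain_id),
                        function(d) data.frame(
                          brain_id = d$brain_id[1],
                          n_cells = nrow(d),
                          mean_net_intensity = mean(d$net_intensity),
                          stringsAsFactors = FALSE)))
}
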