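#' Burst-detection parameters
#'
#' Bursts are peaks of the conditioned, normalized trace with a minimum
#' topographic prominence and a minimum inter-peak distance.  The published
#' threshold (prominence 0.2, distance 15 s) is interpreted on the
#' baseline-normalized trace, where 0.2 means 20% of a typical baseline
#' burst peak; the normalization mode is configurable because the threshold's
#' units are not fixed by the acquisition.
#'
#' @param min_prominence minimum topographic prominence (> 0).
#' @param min_distance_s minimum distance between kept peaks, seconds.
#' @param normalization `"baseline-robust-max"`, `"zscore"` or `"none"`.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_prominence = 0.2, min_distance_s = 15,
                             normalization = c("baseline-robust-max",
                                               "zscore", "none")) {
  normalization <- match.arg(normalization)
  if (min_prominence <= 0) stop("min_prominence must be positive")
  if (min_distance_s <= 0) stop("min_distance_s must be positive")
  structure(list(min_prominence = min_prominence,
                 min_distance_s = min_distance_s,
                 normalization = normalization),
            class = "detection_params")
}

#' Normalize a conditioned trace
#'
#' `"baseline-robust-max"` divides by the 95th percentile of the trace within
#' the baseline window, so a prominence threshold of 0.2 reads as 20% of a
#' typical baseline burst peak and detection is invariant to amplitude
#' scaling.  `"zscore"` is `(x - median) / (1.4826 * MAD)`; `"none"` is the
#' identity.
#'
#' @param rec an [recording()].
#' @param mode normalization mode.
#' @param baseline_window numeric `c(start_s, end_s)` of the baseline used by
#'   `"baseline-robust-max"`.
#' @return The normalized recording.
#' @export
normalize_trace <- function(rec, mode = c("baseline-robust-max", "zscore",
                                          "none"),
                            baseline_window = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "xii_recording"))
  if (mode == "none") return(rec)
  x <- rec$samples
  if (mode == "baseline-robust-max") {
    if (is.null(baseline_window))
      stop("baseline_window is required for baseline-robust-max")
    t <- rec_times(rec)
    inw <- t >= baseline_window[1] & t < baseline_window[2]
    if (!any(inw)) stop("baseline window contains no samples")
    div <- stats::quantile(x[inw], 0.95, names = FALSE)
    if (div <= 0) stop("baseline 95th percentile is not positive")
    y <- x / div
  } else {
    m <- stats::median(x)
    s <- stats::mad(x)  # 1.4826 * MAD
    if (s <= 0) stop("zero MAD: cannot z-score a constant trace")
    y <- (x - m) / s
  }
  recording(y, rec$rate_hz, rec$slice_id, rec$meta)
}

#' Detect bursts on a conditioned, normalized trace
#'
#' Peaks are local maxima with topographic prominence (height above the
#' higher of the two bracketing minima separating the peak from larger
#' peaks) at least `min_prominence`.  Among peaks closer than
#' `min_distance_s` the higher one is kept (ties broken to the earlier).
#' Burst onset/offset are the nearest crossings of
#' `peak - prominence / 2` on either side (linearly interpolated), giving
#' the half-prominence width; per-burst features are then attached with
#' [burst_features()].
#'
#' @param rec conditioned, normalized [recording()].
#' @param params a [detection_params()] (its `normalization` field documents
#'   how `rec` was normalized; no normalization is applied here).
#' @param epoch_label optional epoch label to stamp on all bursts.
#' @return A `burst_table`: a `data.frame` with one row per burst and columns
#'   `slice_id`, `epoch_label`, `peak_t_s`, `onset_t_s`, `offset_t_s`,
#'   `height`, `width_s`, `area`, `period_to_next_s`, `flag`.
#' @export
detect_bursts <- function(rec, params = detection_params(),
                          epoch_label = NA_character_) {
  stopifnot(inherits(rec, "xii_recording"),
            inherits(params, "detection_params"))
  x <- rec$samples
  empty <- burst_table_empty(rec$slice_id)
  if (length(x) < 3) return(empty)
  pk <- .peaks_cpp(x)
  pk <- pk[pk$prominence >= params$min_prominence, , drop = FALSE]
  if (nrow(pk) == 0) return(empty)
  # min-distance rule: keep the higher, ties to the earlier
  ord <- order(-pk$height, pk$index)
  keep <- logical(nrow(pk))
  kept_t <- numeric(0)
  min_gap <- params$min_distance_s * rec$rate_hz
  for (i in ord) {
    if (all(abs(pk$index[i] - kept_t) >= min_gap)) {
      keep[i] <- TRUE
      kept_t <- c(kept_t, pk$index[i])
    }
  }
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk$index), , drop = FALSE]

  # onset/offset at the half-prominence crossing nearest the peak
  lvl <- pk$height - pk$prominence / 2
  onset <- offset <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    p <- pk$index[i]; L <- lvl[i]
    j <- p
    while (j > 1 && x[j] > L) j <- j - 1
    onset[i] <- if (x[j] > L) j else
      j + (L - x[j]) / (x[j + 1] - x[j])  # interpolate on [j, j+1]
    j <- p
    n <- length(x)
    while (j < n && x[j] > L) j <- j + 1
    offset[i] <- if (x[j] > L) j else
      j - (L - x[j]) / (x[j - 1] - x[j])
  }
  tab <- data.frame(
    slice_id = rec$slice_id,
    epoch_label = epoch_label,
    peak_t_s = (pk$index - 1) / rec$rate_hz,
    onset_t_s = (onset - 1) / rec$rate_hz,
    offset_t_s = (offset - 1) / rec$rate_hz,
    height = pk$height,
    width_s = NA_real_, area = NA_real_,
    period_to_next_s = NA_real_,
    flag = FALSE,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("burst_table", "data.frame")
  burst_features(rec, tab)
}

burst_table_empty <- function(slice_id = character(0)) {
  tab <- data.frame(slice_id = character(0), epoch_label = character(0),
                    peak_t_s = numeric(0), onset_t_s = numeric(0),
                    offset_t_s = numeric(0), height = numeric(0),
                    width_s = numeric(0), area = numeric(0),
                    period_to_next_s = numeric(0), flag = logical(0),
                    stringsAsFactors = FALSE)
  class(tab) <- c("burst_table", "data.frame")
  tab
}

#' Per-burst features
#'
#' For each burst: `height` is the trace maximum in `[onset, offset]`,
#' `width_s` the half-prominence width `offset - onset`, and `area` the sum
#' of trace samples within `[onset, offset]` divided by the sampling rate
#' (the within-burst integral of the conditioned trace).  Periods are the
#' successive peak-time differences.
#'
#' @param rec the conditioned [recording()] the bursts were detected on.
#' @param table a `burst_table` with onset/offset columns.
#' @return The table with `height`, `width_s`, `area` and
#'   `period_to_next_s` filled in.
#' @export
burst_features <- function(rec, table) {
  if (nrow(table) == 0) return(table)
  r <- rec$rate_hz
  n <- length(rec$samples)
  for (i in seq_len(nrow(table))) {
    # samples whose time (i-1)/r lies in [onset, offset]
    ia <- max(1L, as.integer(ceiling(table$onset_t_s[i] * r - 1e-9)) + 1L)
    ib <- min(n, as.integer(floor(table$offset_t_s[i] * r + 1e-9)) + 1L)
    v <- rec$samples[ia:ib]
    table$height[i] <- max(v)
    table$area[i] <- sum(v) / r
  }
  table$width_s <- table$offset_t_s - table$onset_t_s
  table$period_to_next_s <-
    c(diff(table$peak_t_s), NA_real_)
  table
}

#' Plausibility screen for detected bursts
#'
#' Replaces the manual false-positive check with an auditable mechanism:
#' bursts whose width or height falls outside the plausibility bands get
#' `flag = TRUE` but are never removed; exclusion is only ever done
#' explicitly by the analyst via the returned report.
#'
#' @param table a `burst_table` with features.
#' @param width_band,height_band numeric `c(lo, hi)` plausibility bands.
#' @return The table with `flag` set; the flagged subset is attached as
#'   attribute `"review"` for human review.
#' @export
screen_bursts <- function(table, width_band = c(0.1, 5),
                          height_band = c(0, Inf)) {
  if (nrow(table) == 0) return(table)
  bad <- table$width_s < width_band[1] | table$width_s > width_band[2] |
    table$height < height_band[1] | table$height > height_band[2]
  table$flag <- bad
  attr(table, "review") <- table[bad, , drop = FALSE]
  table
}

#' Explicitly reject flagged bursts
#'
#' The analyst's accept/reject step after reviewing [screen_bursts()] flags:
#' removes flagged rows and recomputes `period_to_next_s` from the remaining
#' peak times (periods must be refreshed once false positives between two
#' true bursts are gone).
#'
#' @param table a screened `burst_table`.
#' @return The table without flagged rows, periods recomputed.
#' @export
drop_rejected <- function(table) {
  out <- table[!table$flag, , drop = FALSE]
  if (nrow(out)) {
    out$period_to_next_s <- c(diff(out$peak_t_s), NA_real_)
    rownames(out) <- NULL
  }
  out
}
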