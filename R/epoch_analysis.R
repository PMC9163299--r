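#' Assign bursts to analysis epochs
#'
#' A burst belongs to epoch e iff its peak time lies in
#' `[analysis_start_s, end_s)` of e.  A period straddling an epoch boundary
#' is kept (attributed to the earlier burst) only when both bursts fall in
#' the same analysis window; otherwise the period is dropped (set `NA`).
#' Bursts outside every analysis window keep `epoch_label = NA` and are
#' counted in attribute `"n_unassigned"`.
#'
#' @param table a `burst_table`.
#' @param plan an [epoch_plan()].
#' @return The table with `epoch_label` filled and straddling periods
#'   removed.
#' @export
assign_epochs <- function(table, plan) {
  stopifnot(inherits(plan, "epoch_plan"))
  if (nrow(table) == 0) return(table)
  lab <- rep(NA_character_, nrow(table))
  for (k in seq_len(nrow(plan))) {
    inw <- table$peak_t_s >= plan$analysis_start_s[k] &
      table$peak_t_s < plan$end_s[k]
    lab[inw] <- plan$label[k]
  }
  table$epoch_label <- lab
  nxt <- c(lab[-1], NA_character_)
  same <- !is.na(lab) & !is.na(nxt) & lab == nxt
  table$period_to_next_s[!same] <- NA_real_
  n_un <- sum(is.na(lab))
  if (n_un > 0)
    message(n_un, " burst(s) outside all analysis windows were left unassigned")
  attr(table, "n_unassigned") <- n_un
  table
}

#' Summarize one epoch's bursts
#'
#' Arithmetic means of the per-burst features and the coefficient of
#' variation of the period (sample SD / mean; sample SD uses n-1 because
#' per-epoch burst counts are small).  Period statistics need at least one
#' valid period (two bursts); the CV needs at least two.
#'
#' @param bursts a `burst_table` subset (one slice, one epoch).
#' @return A one-row `data.frame` with `n_bursts`, `mean_period_s`,
#'   `mean_height`, `mean_width_s`, `mean_area`, `cv_period`.
#' @export
summarize_epoch <- function(bursts) {
  per <- bursts$period_to_next_s
  per <- per[!is.na(per)]
  data.frame(
    n_bursts = nrow(bursts),
    mean_period_s = if (length(per) >= 1) mean(per) else NA_real_,
    mean_height = if (nrow(bursts)) mean(bursts$height) else NA_real_,
    mean_width_s = if (nrow(bursts)) mean(bursts$width_s) else NA_real_,
    mean_area = if (nrow(bursts)) mean(bursts$area) else NA_real_,
    cv_period = if (length(per) >= 2) stats::sd(per) / mean(per) else NA_real_
  )
}

#' Summarize all epochs of a burst table
#'
#' @param table a `burst_table` whose `epoch_label` has been filled by
#'   [assign_epochs()] (rows with `NA` labels are ignored).
#' @param plan optional [epoch_plan()] fixing the epoch order.
#' @return A `data.frame`, one row per slice x epoch, of class
#'   `epoch_summary`.
#' @export
summarize_epochs <- function(table, plan = NULL) {
  tab <- table[!is.na(table$epoch_label), , drop = FALSE]
  labs <- if (!is.null(plan)) plan$label else unique(tab$epoch_label)
  out <- do.call(rbind, lapply(split(tab, tab$slice_id), function(ts) {
    rows <- lapply(intersect(labs, unique(ts$epoch_label)), function(l) {
      s <- summarize_epoch(ts[ts$epoch_label == l, , drop = FALSE])
      cbind(data.frame(slice_id = ts$slice_id[1], epoch_label = l,
                       stringsAsFactors = FALSE), s)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  class(out) <- c("epoch_summary", "data.frame")
  out
}

#' Normalize epoch summaries to the baseline epoch
#'
#' Per slice, each epoch mean is divided by the slice's baseline mean
#' (`normalized_x = mean_x / mean_x(baseline)`), and the period
#' irregularity change is `delta_cv = cv_period - cv_period(baseline)`.
#' Baseline rows therefore get normalized values of exactly 1 and
#' `delta_cv = 0`.
#'
#' @param summaries an `epoch_summary` table containing a baseline row for
#'   every slice.
#' @return The table with `normalized_period`, `normalized_height`,
#'   `normalized_width`, `normalized_area` and `delta_cv` columns added.
#' @export
normalize_to_baseline <- function(summaries) {
  out <- do.call(rbind, lapply(split(summaries, summaries$slice_id),
                               function(s) {
    b <- s[s$epoch_label == "baseline", , drop = FALSE]
    if (nrow(b) != 1)
      stop("slice ", s$slice_id[1], " lacks a baseline summary")
    for (v in c("period_s", "height", "width_s", "area")) {
      mv <- b[[paste0("mean_", v)]]
      if (!is.finite(mv) || mv == 0)
        stop("zero or missing baseline mean_", v, " for slice ",
             s$slice_id[1])
      s[[paste0("normalized_", sub("_s$", "", v))]] <-
        s[[paste0("mean_", v)]] / mv
    }
    s$delta_cv <- s$cv_period - b$cv_period
    s
  }))
  rownames(out) <- NULL
  class(out) <- c("epoch_summary", "data.frame")
  out
}
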