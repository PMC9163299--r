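#' Sampled single-channel recording
#'
#' Container for a uniformly sampled extracellular voltage trace, e.g. the
#' integrated hypoglossal (XII) rootlet signal of a rhythmic slice
#' preparation.  Time is measured in seconds with t = 0 at the first sample;
#' amplitude units are arbitrary (downstream analysis normalizes to the
#' baseline epoch, so no gain correction is assumed).
#'
#' @param samples numeric vector of samples; must be non-empty and free of
#'   missing values (the loader rejects rather than imputes).
#' @param rate_hz sampling rate in samples per second (> 0).
#' @param slice_id identifier of the slice/preparation.
#' @param meta named list of free-form metadata (strain, age, condition
#'   notes, processing provenance).
#' @return An object of class `xii_recording`.
#' @export
recording <- function(samples, rate_hz, slice_id = "slice", meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording must contain at least one sample")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("recording contains missing or non-finite samples")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         slice_id = as.character(slice_id), meta = meta),
    class = "xii_recording"
  )
}

#' @export
print.xii_recording <- function(x, ...) {
  cat(sprintf("<xii_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$slice_id, length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz))
  invisible(x)
}

#' @export
length.xii_recording <- function(x) length(x$samples)

#' Sample times of a recording
#'
#' @param rec an [recording()] object.
#' @return numeric vector of times in seconds, t = 0 at the first sample.
#' @export
rec_times <- function(rec) {
  (seq_along(rec$samples) - 1) / rec$rate_hz
}

#' Write a recording to disk
#'
#' Two plain formats are supported: `"delimited"` (one sample per line with
#' `# key=value` header lines for the rate and slice id) and `"binary"`
#' (raw little-endian 32-bit floats in `<path>.f32` with a JSON sidecar
#' `<path>.json` holding `rate_hz`, `slice_id` and `meta`).
#'
#' @param rec an [recording()] object.
#' @param path output path; for the binary format the extensions `.f32` and
#'   `.json` are appended to `path` stripped of any `.f32` suffix.
#' @param format `"delimited"` or `"binary"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "xii_recording"))
  if (format == "delimited") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# rate_hz=%.17g", rec$rate_hz),
                 sprintf("# slice_id=%s", rec$slice_id)), con)
    writeLines(formatC(rec$samples, format = "g", digits = 17), con)
  } else {
    stem <- sub("\\.f32$", "", path)
    con <- file(paste0(stem, ".f32"), "wb")
    writeBin(rec$samples, con, size = 4L, endian = "little")
    close(con)
    jsonlite::write_json(
      list(rate_hz = rec$rate_hz, slice_id = rec$slice_id, meta = rec$meta),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load a recording from disk
#'
#' @param path file path (for the binary format, the `.f32` file or its stem;
#'   the JSON sidecar must sit next to it).
#' @param format `"delimited"` or `"binary"`; default guesses from the
#'   extension (`.f32` means binary).
#' @return An [recording()] object.  The loader is strict: a missing sampling
#'   rate is an error, and any non-numeric or missing sample row is an error
#'   naming the offending row.
#' @export
load_recording <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.f32$", path) || file.exists(paste0(path, ".f32")))
      "binary" else "delimited"
  format <- match.arg(format, c("delimited", "binary"))
  if (format == "delimited") {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    rate <- NA_real_; slice_id <- "slice"
    for (h in lines[hdr]) {
      kv <- sub("^#\\s*", "", h)
      if (grepl("^rate_hz=", kv)) rate <- as.numeric(sub("^rate_hz=", "", kv))
      if (grepl("^slice_id=", kv)) slice_id <- sub("^slice_id=", "", kv)
    }
    if (is.na(rate)) stop("delimited recording lacks a '# rate_hz=' header")
    body <- if (length(hdr)) lines[-hdr] else lines
    body <- body[nzchar(trimws(body))]
    vals <- suppressWarnings(as.numeric(body))
    bad <- which(is.na(vals))
    if (length(bad))
      stop(sprintf("non-numeric or missing sample at data row %d: '%s'",
                   bad[1], body[bad[1]]))
    recording(vals, rate, slice_id)
  } else {
    stem <- sub("\\.f32$", "", path)
    f32 <- paste0(stem, ".f32"); sidecar <- paste0(stem, ".json")
    if (!file.exists(f32)) stop("no such file: ", f32)
    if (!file.exists(sidecar))
      stop("binary recording requires JSON sidecar: ", sidecar)
    metaj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(metaj$rate_hz)) stop("sidecar lacks rate_hz")
    n <- file.info(f32)$size / 4L
    con <- file(f32, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = n, size = 4L, endian = "little")
    if (anyNA(vals)) stop("binary recording contains NaN at sample ",
                          which(is.na(vals))[1])
    recording(vals, metaj$rate_hz,
              slice_id = metaj$slice_id %||% "slice",
              meta = as.list(metaj$meta %||% list()))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Epoch plan: labelled drug-exposure intervals
#'
#' An epoch plan partitions a recording into labelled half-open intervals
#' `[start_s, end_s)`, one per condition, each with an analysis window
#' starting at `analysis_start_s` (bursts before it are ignored, allowing the
#' rhythm to stabilize after a drug wash-in).  Exactly one epoch must be
#' labelled `"baseline"`.
#'
#' @param label,start_s,end_s,analysis_start_s equal-length vectors defining
#'   the epochs.
#' @return A `data.frame` of class `epoch_plan`.
#' @export
epoch_plan <- function(label, start_s, end_s, analysis_start_s = start_s) {
  p <- data.frame(label = as.character(label),
                  start_s = as.numeric(start_s),
                  end_s = as.numeric(end_s),
                  analysis_start_s = as.numeric(analysis_start_s),
                  stringsAsFactors = FALSE)
  if (nrow(p) == 0L) stop("epoch plan must contain at least one epoch")
  if (any(p$end_s <= p$start_s)) stop("epochs must satisfy start_s < end_s")
  if (any(p$analysis_start_s < p$start_s | p$analysis_start_s >= p$end_s))
    stop("analysis_start_s must lie in [start_s, end_s)")
  if (is.unsorted(p$start_s, strictly = TRUE))
    stop("epochs must be ordered by start time")
  if (any(utils::head(p$end_s, -1) > utils::tail(p$start_s, -1) + 1e-12))
    stop("epochs must not overlap")
  if (sum(p$label == "baseline") != 1L)
    stop("exactly one epoch must be labelled 'baseline'")
  class(p) <- c("epoch_plan", "data.frame")
  p
}

#' Default recording protocol epoch plan
#'
#' Builds the standard slice-pharmacology protocol: a baseline epoch analyzed
#' in full, followed by one drug epoch per label, each `drug_min` minutes
#' long with only its final `analyzed_min` minutes analyzed (rhythm
#' stabilization after wash-in).
#'
#' @param labels character vector of drug epoch labels (order = application
#'   order).
#' @param baseline_min baseline duration in minutes (default 10).
#' @param drug_min duration of each drug exposure in minutes (default 20).
#' @param analyzed_min analyzed tail of each drug epoch in minutes
#'   (default 10); must not exceed `drug_min`.
#' @return An [epoch_plan()].
#' @export
default_epoch_plan <- function(labels, baseline_min = 10, drug_min = 20,
                               analyzed_min = 10) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (analyzed_min > drug_min)
    stop("analyzed_min must not exceed drug_min")
  b <- baseline_min * 60
  d <- drug_min * 60
  a <- analyzed_min * 60
  starts <- b + (seq_along(labels) - 1) * d
  epoch_plan(label = c("baseline", labels),
             start_s = c(0, starts),
             end_s = c(b, starts + d),
             analysis_start_s = c(0, starts + d - a))
}

#' Read / write an epoch plan as JSON
#'
#' @param plan an [epoch_plan()].
#' @param path JSON file path.
#' @return `read_epoch_plan` returns an [epoch_plan()]; `write_epoch_plan`
#'   returns `path` invisibly.
#' @export
write_epoch_plan <- function(plan, path) {
  jsonlite::write_json(as.data.frame(unclass(plan)), path, digits = NA)
  invisible(path)
}

#' @rdname write_epoch_plan
#' @export
read_epoch_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  epoch_plan(p$label, p$start_s, p$end_s, p$analysis_start_s)
}
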