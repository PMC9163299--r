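#' Trace-conditioning parameters
#'
#' Defaults reproduce the analysis settings for 20 kHz XII rootlet
#' acquisitions: resample at 1/10 rate, Hampel artifact filter with a 0.5 s
#' window and a 5-sigma threshold, and a leaky integrator with per-sample
#' decay 0.98 (applied at the post-decimation rate).
#'
#' @param decimation_factor positive integer resampling factor.
#' @param hampel_window_s total width of the centered Hampel window, seconds.
#' @param hampel_nsigma Hampel threshold in scaled-MAD units.
#' @param leak_decay leaky-integrator per-sample decay, in (0, 1).
#' @return A list of class `conditioning_params`.
#' @export
conditioning_params <- function(decimation_factor = 10L,
                                hampel_window_s = 0.5,
                                hampel_nsigma = 5,
                                leak_decay = 0.98) {
  decimation_factor <- as.integer(decimation_factor)
  if (decimation_factor < 1L) stop("decimation_factor must be >= 1")
  if (hampel_window_s <= 0) stop("hampel_window_s must be positive")
  if (hampel_nsigma <= 0) stop("hampel_nsigma must be positive")
  if (leak_decay <= 0 || leak_decay >= 1) stop("leak_decay must be in (0, 1)")
  structure(list(decimation_factor = decimation_factor,
                 hampel_window_s = hampel_window_s,
                 hampel_nsigma = hampel_nsigma,
                 leak_decay = leak_decay),
            class = "conditioning_params")
}

#' Decimate a recording
#'
#' Anti-aliased resampling at 1/factor rate: a centered moving average of
#' width `factor` (truncated at the edges) followed by take-every-kth,
#' keeping the first sample of each block.  `factor = 1` is the identity.
#'
#' @param rec an [recording()].
#' @param factor positive integer, at most the number of samples.
#' @return A recording with `rate_hz / factor` and `floor(n / factor)`
#'   samples.
#' @export
decimate <- function(rec, factor) {
  stopifnot(inherits(rec, "xii_recording"))
  factor <- as.integer(factor)
  n <- length(rec$samples)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor > n) stop("decimation factor exceeds recording length")
  if (factor == 1L) return(rec)
  x <- rec$samples
  # centered moving average of width `factor` via cumulative sums
  half_lo <- (factor - 1L) %/% 2L
  half_hi <- factor - 1L - half_lo
  cs <- cumsum(c(0, x))
  keep <- (seq_len(n %/% factor) - 1L) * factor + 1L
  lo <- pmax(keep - half_lo, 1L)
  hi <- pmin(keep + half_hi, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  recording(sm, rec$rate_hz / factor, rec$slice_id, rec$meta)
}

#' Hampel artifact filter
#'
#' Flags sample i when `|x_i - median_i| > nsigma * 1.4826 * MAD_i` over a
#' centered window, and replaces flagged samples by the window median
#' (replacement rather than deletion keeps the time base intact, which burst
#' periods depend on).  Windows with zero MAD (locally constant data) flag
#' nothing.  The replacement median is computed from the original samples.
#'
#' @param rec an [recording()].
#' @param window_s total window width in seconds; must span at least 3
#'   samples at the recording's rate.
#' @param nsigma threshold in scaled-MAD ("standard deviation") units.
#' @return A list with `rec` (filtered recording) and `flagged`
#'   (1-based indices of replaced samples).
#' @export
hampel_filter <- function(rec, window_s = 0.5, nsigma = 5) {
  stopifnot(inherits(rec, "xii_recording"))
  h <- floor(window_s * rec$rate_hz / 2)
  if (2 * h + 1 < 3)
    stop("hampel window spans fewer than 3 samples at this rate")
  res <- .hampel_cpp(rec$samples, as.integer(h), nsigma)
  out <- recording(res$y, rec$rate_hz, rec$slice_id, rec$meta)
  list(rec = out, flagged = as.integer(res$flagged))
}

#' Rectified leaky integrator
#'
#' First-order recursive envelope `y[n] = decay * y[n-1] + |x[n]|` with
#' `y[1] = |x[1]|` — the classic "integrated XII" trace.  The input is
#' rectified first because the extracellular signal is AC-coupled and would
#' otherwise cancel.  The decay is a dimensionless per-sample multiplier.
#'
#' @param rec an [recording()].
#' @param decay per-sample decay constant in (0, 1).
#' @return The integrated recording at the same rate.
#' @export
leaky_integrate <- function(rec, decay = 0.98) {
  stopifnot(inherits(rec, "xii_recording"))
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)")
  y <- as.numeric(stats::filter(abs(rec$samples), decay, method = "recursive"))
  recording(y, rec$rate_hz, rec$slice_id, rec$meta)
}

#' Condition a raw trace for burst detection
#'
#' The full conditioning chain, in order: [decimate()] (resampling listed
#' before artifact exclusion), [hampel_filter()] (window interpreted at the
#' post-decimation rate), [leaky_integrate()].  Indices of Hampel-replaced
#' samples are recorded in `meta$hampel_flagged` of the result.
#'
#' @param rec an [recording()].
#' @param params a [conditioning_params()].
#' @return The conditioned (integrated) recording.
#' @export
condition <- function(rec, params = conditioning_params()) {
  stopifnot(inherits(params, "conditioning_params"))
  dec <- decimate(rec, params$decimation_factor)
  hf <- hampel_filter(dec, params$hampel_window_s, params$hampel_nsigma)
  out <- leaky_integrate(hf$rec, params$leak_decay)
  out$meta$hampel_flagged <- hf$flagged
  out
}
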