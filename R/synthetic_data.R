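#' Synthetic-recording configuration
#'
#' Parameters of the burstlet-train generator that emulates XII rootlet
#' rhythm: gamma-distributed burstlet intervals (positive, CV-parameterized)
#' whose mean is the baseline period scaled by the dose model's per-epoch
#' multiplier; Bernoulli transmission failure (dropout) that leaves observed
#' burst periods at integer multiples of the burstlet period; a
#' double-exponential burst kernel riding on Gaussian noise; and a gradual
#' fractional amplitude rundown.  Defaults are the study conditions: 0.04 Hz
#' baseline rhythm (period 25 s, leaving both dose arms clear of the 15 s
#' minimum peak distance the detection stage uses), interval CV 0.10, no
#' dropout, kernel rise
#' 0.05 s / decay 0.3 s with unit peak, rundown 1%/min, noise SD 0.05 (5% of
#' the peak), 2 kHz sampling (a post-decimation-equivalent rate; set 20 kHz
#' for raw-acquisition emulation).
#'
#' @param seed integer; all randomness of the generator flows from it.
#' @param rate_hz sampling rate of synthesized traces.
#' @param baseline_period_s mean burstlet period at baseline.
#' @param jitter_cv CV of burstlet intervals.
#' @param dropout_p burstlet transmission-failure probability in `[0, 1)`.
#' @param burst_rise_s,burst_decay_s,peak_amp burst kernel shape.
#' @param rundown_per_min fractional amplitude decline per minute.
#' @param noise_sd Gaussian noise SD (trace units).
#' @param dose_model a [dose_response_model()] mapping epoch drug
#'   concentrations to period multipliers.
#' @param epoch_plan an [epoch_plan()]; epoch labels of the form
#'   `"<conc>nM"` (e.g. `"PGE2_10nM"`) are parsed for the dose model, label
#'   `"baseline"` gets multiplier 1.
#' @param cv_scale named numeric: per-epoch multiplicative scaling of
#'   `jitter_cv` (irregularity knob emulating the observed CV increase at
#'   10 nM); unnamed epochs get 1.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, rate_hz = 2000, baseline_period_s = 25,
                         jitter_cv = 0.10, dropout_p = 0,
                         burst_rise_s = 0.05, burst_decay_s = 0.3,
                         peak_amp = 1, rundown_per_min = 0.01,
                         noise_sd = 0.05,
                         dose_model = dose_response_model(),
                         epoch_plan = default_epoch_plan("PGE2_10nM"),
                         cv_scale = numeric(0)) {
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  if (jitter_cv < 0) stop("jitter_cv must be >= 0")
  if (baseline_period_s <= 0) stop("baseline_period_s must be positive")
  structure(list(seed = as.integer(seed), rate_hz = rate_hz,
                 baseline_period_s = baseline_period_s,
                 jitter_cv = jitter_cv, dropout_p = dropout_p,
                 burst_rise_s = burst_rise_s, burst_decay_s = burst_decay_s,
                 peak_amp = peak_amp, rundown_per_min = rundown_per_min,
                 noise_sd = noise_sd, dose_model = dose_model,
                 epoch_plan = epoch_plan, cv_scale = cv_scale),
            class = "synth_config")
}

# concentration (nM) parsed from an epoch label like "PGE2_10nM"; NA if none
parse_conc_nM <- function(label) {
  m <- regmatches(label, regexpr("[0-9.]+?(?=\\s*nM)", label, perl = TRUE))
  if (length(m) && nzchar(m)) as.numeric(m) else NA_real_
}

epoch_multiplier <- function(cfg, label) {
  if (label == "baseline") return(1)
  conc <- parse_conc_nM(label)
  if (is.na(conc)) return(1)
  biphasic_profile(cfg$dose_model, conc)
}

#' Draw gamma-distributed burstlet intervals
#'
#' @param n number of intervals.
#' @param mean_s mean interval.
#' @param cv coefficient of variation; `cv = 0` gives deterministic
#'   intervals.
#' @return Numeric vector of positive intervals.
#' @keywords internal
draw_intervals <- function(n, mean_s, cv) {
  if (cv == 0) return(rep(mean_s, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean_s)
}

#' Generate an observed burst-period sample with burstlet dropout
#'
#' Burstlet intervals are gamma with mean `baseline_period_s *
#' dose-multiplier(epoch)` and CV `jitter_cv`; each burstlet is transmitted
#' (becomes a full XII burst) with probability `1 - dropout_p`.  Observed
#' periods are the gaps between consecutive transmitted events, so dropout
#' yields sums of k consecutive intervals and the period distribution
#' develops modes near integer multiples of the burstlet period.
#'
#' @param cfg a [synth_config()].
#' @param n number of observed periods to return.
#' @param epoch_label epoch whose dose multiplier applies (default
#'   `"baseline"`).
#' @return A list: `periods` (length `n`), and `ground_truth` with
#'   `event_times_s` (all burstlets), `transmitted_times_s`, `multiplier`,
#'   `true_mean_period_s` (burstlet-level), `true_cv`.
#' @export
generate_period_sample <- function(cfg, n, epoch_label = "baseline") {
  stopifnot(inherits(cfg, "synth_config"), n >= 1)
  set.seed(cfg$seed)
  mult <- epoch_multiplier(cfg, epoch_label)
  cvs <- if (epoch_label %in% names(cfg$cv_scale))
    cfg$cv_scale[[epoch_label]] else 1
  cv <- cfg$jitter_cv * cvs
  mean_s <- cfg$baseline_period_s * mult
  # enough burstlets that >= n+1 survive thinning
  n_ev <- ceiling((n + 2) / (1 - cfg$dropout_p) * 1.3) + 20
  repeat {
    iv <- draw_intervals(n_ev, mean_s, cv)
    ev <- cumsum(iv)
    keep <- stats::runif(n_ev) >= cfg$dropout_p
    tr <- ev[keep]
    if (length(tr) >= n + 1) break
    n_ev <- n_ev * 2
  }
  periods <- diff(tr)[seq_len(n)]
  list(periods = periods,
       ground_truth = list(event_times_s = ev, transmitted_times_s = tr,
                           multiplier = mult, true_mean_period_s = mean_s,
                           true_cv = cv))
}

# double-exponential kernel sampled at dt, normalized to peak 1;
# attribute "peak_i" is the sample index of the maximum
burst_kernel <- function(rise_s, decay_s, rate_hz) {
  t_max <- rise_s + decay_s * 12
  t <- seq(0, t_max, by = 1 / rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  structure(k / max(k), peak_i = which.max(k))
}

#' Synthesize a full XII-like recording
#'
#' Lays down the burstlet train across the whole epoch plan (inter-event
#' intervals drawn per epoch with that epoch's dose multiplier), thins it by
#' the dropout probability, and renders each transmitted event as a
#' double-exponential burst scaled by `peak_amp * (1 - rundown_per_min *
#' t/60)`, plus Gaussian noise.
#'
#' @param cfg a [synth_config()].
#' @param slice_id identifier stamped on the recording.
#' @return A list: `rec` (an [recording()]) and `ground_truth`
#'   (`event_times_s`, `transmitted_times_s`, per-epoch `multipliers`,
#'   per-epoch true mean period and CV).
#' @export
synthesize_recording <- function(cfg, slice_id = "synthetic") {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  plan <- cfg$epoch_plan
  total_s <- max(plan$end_s)
  ev <- numeric(0)
  mults <- setNames(numeric(nrow(plan)), plan$label)
  tms <- setNames(numeric(nrow(plan)), plan$label)
  tcv <- setNames(numeric(nrow(plan)), plan$label)
  t_cur <- 0
  for (k in seq_len(nrow(plan))) {
    lab <- plan$label[k]
    mult <- epoch_multiplier(cfg, lab)
    cvs <- if (lab %in% names(cfg$cv_scale)) cfg$cv_scale[[lab]] else 1
    cv <- cfg$jitter_cv * cvs
    mean_s <- cfg$baseline_period_s * mult
    mults[k] <- mult; tms[k] <- mean_s; tcv[k] <- cv
    while (t_cur < plan$end_s[k]) {
      t_cur <- t_cur + draw_intervals(1, mean_s, cv)
      if (t_cur < plan$end_s[k]) ev <- c(ev, t_cur)
    }
    t_cur <- max(t_cur, plan$end_s[k])
  }
  keep <- stats::runif(length(ev)) >= cfg$dropout_p
  tr <- ev[keep]
  n <- ceiling(total_s * cfg$rate_hz)
  x <- numeric(n)
  kern <- burst_kernel(cfg$burst_rise_s, cfg$burst_decay_s, cfg$rate_hz)
  kl <- length(kern)
  eff_w <- cfg$burst_rise_s + 3 * cfg$burst_decay_s  # kernel down to ~5% peak
  if (length(tr) > 1 && min(diff(tr)) < eff_w)
    warning("burst kernel is wider than the smallest event spacing")
  pk_i <- attr(kern, "peak_i")
  for (tt in tr) {
    # align the kernel's peak with the event time
    i0 <- floor(tt * cfg$rate_hz) + 2L - pk_i
    if (i0 > n) next
    if (i0 < 1) { kern_off <- 2L - i0; i0 <- 1L } else kern_off <- 1L
    # fractional decline compounds per minute (signal-to-noise loss is
    # gradual; amplitude never reaches exactly zero)
    amp <- cfg$peak_amp * (1 - cfg$rundown_per_min)^(tt / 60)
    ii <- i0:min(n, i0 + (kl - kern_off))
    x[ii] <- x[ii] + amp * kern[kern_off + seq_along(ii) - 1L]
  }
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  rec <- recording(x, cfg$rate_hz, slice_id,
                   meta = list(synthetic = TRUE, seed = cfg$seed))
  list(rec = rec,
       ground_truth = list(event_times_s = ev, transmitted_times_s = tr,
                           multipliers = mults, true_mean_period_s = tms,
                           true_cv = tcv))
}

#' Simulate a multi-slice experiment battery
#'
#' Per-slice baseline periods are drawn lognormal across slices (biological
#' heterogeneity); all slices share the condition multipliers.  For each
#' slice x condition a finite sample of observed periods is generated and
#' the condition response is its mean period normalized to the slice's
#' baseline mean — the input schema of the group-inference layer.
#'
#' @param n_slices number of slices (clusters), >= 2.
#' @param conditions named numeric of period multipliers per condition.
#' @param cfg template [synth_config()]; its `baseline_period_s` is the
#'   lognormal median across slices.
#' @param seed integer seed.
#' @param n_periods periods sampled per slice x condition (default 60).
#' @param sdlog between-slice lognormal SD of the baseline period
#'   (default 0.2).
#' @return A list: `data` (data.frame `slice_id`, `condition`, `response` =
#'   normalized mean period) and `ground_truth` (the multipliers).
#' @export
simulate_experiment_battery <- function(n_slices, conditions,
                                        cfg = synth_config(), seed = 1L,
                                        n_periods = 60, sdlog = 0.2) {
  stopifnot(n_slices >= 2)
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_slices)) {
    base <- stats::rlnorm(1, log(cfg$baseline_period_s), sdlog)
    base_periods <- draw_intervals(n_periods, base, cfg$jitter_cv)
    base_mean <- mean(base_periods)
    for (cn in names(conditions)) {
      per <- draw_intervals(n_periods, base * conditions[[cn]],
                            cfg$jitter_cv)
      rows[[length(rows) + 1]] <- data.frame(
        slice_id = sprintf("slice%02d", s), condition = cn,
        response = mean(per) / base_mean, stringsAsFactors = FALSE)
    }
  }
  list(data = do.call(rbind, rows),
       ground_truth = list(multipliers = conditions))
}
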