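# Brute-force oracles shipped with the package (inst/oracle/): the LP-based
# dip reference (dip_oracle) and the naive sliding median/MAD Hampel
# reference (hampel_oracle_naive).
source(system.file("oracle", "dip_oracle.R", package = "xiirhythm"))
hampel_oracle <- hampel_oracle_naive

# recording with gaussian bumps at given times (seconds)
bump_trace <- function(times, rate = 100, dur = max(times) + 5, amp = 1,
                       sd_s = 0.5, noise = 0, baseline = 0) {
  t <- seq(0, dur, by = 1 / rate)
  x <- rep(baseline, length(t))
  for (tt in times) x <- x + amp * exp(-(t - tt)^2 / (2 * sd_s^2))
  if (noise > 0) x <- x + rnorm(length(t), 0, noise)
  recording(x, rate)
}
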