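---
title: "Methods: burst-rhythm analysis of XII rootlet recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst-rhythm analysis of XII rootlet recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Rhythmic medullary slice preparations expose the inspiratory rhythm of the
preBötzinger complex (preBötC) through bursts on the hypoglossal (XII) nerve
rootlets. Prostaglandin E2 (PGE2) modulates this rhythm biphasically:
nanomolar concentrations lengthen the burst period and make it more
irregular, micromolar concentrations shorten it. Two scientific questions
drive the analysis this package implements:

1. **Dose response of the burst period.** How do per-epoch burst statistics
   (period, height, width, area, period CV), normalized to each slice's
   baseline, change across drug conditions, and are the changes significant
   under repeated-measures inference?
2. **Rhythm vs pattern generation.** Under burstlet theory, rhythm timing
   (burstlets) and burst pattern generation are separable. If a drug lowers
   the probability that a burstlet is transmitted into a full XII burst
   ("dropout"), observed periods become sums of consecutive burstlet
   intervals and the period distribution turns multimodal with modes at
   integer multiples of the burstlet period. If instead the drug slows the
   rhythm generator, the distribution shifts or broadens but stays unimodal.
   Hartigan's dip test distinguishes the two.

Because raw recordings of this kind are rarely deposited, the package pairs
the analysis pipeline with a synthetic-recording generator that has the same
statistical structure, giving every stage a ground truth to be tested
against.

## Pipeline and parameters

Raw traces (acquired at 20,000 samples/s) pass through:

* **Decimation** (`decimate`, default factor 10): centered moving average of
  width equal to the factor (cheap anti-alias, phase preserving), then
  take-every-kth. Output rate 2 kHz for a 20 kHz input.
* **Hampel artifact filter** (`hampel_filter`, default 0.5 s window, 5
  sigma): a sample is flagged when it deviates from its centered-window
  median by more than `5 * 1.4826 * MAD` and is replaced by that median.
  Replacement (not deletion) keeps the time base intact, which burst periods
  depend on; flagged indices are returned for audit. Windows are truncated
  at the trace edges. When the window MAD is zero (locally constant data)
  the rule degenerates to "any nonzero deviation is an artifact", which
  flags a lone spike among constant samples and flags nothing on truly
  constant data.
* **Rectified leaky integration** (`leaky_integrate`, default decay 0.98 per
  post-decimation sample): `y[n] = 0.98 y[n-1] + |x[n]|`, the classic
  integrated-XII envelope. Rectification precedes integration because the
  extracellular signal is AC-coupled and would otherwise cancel. Whether
  the original analysis rectified, and at which rate the decay applies, is
  not derivable from the published parameter alone; both are configuration
  choices here, with the decay read as a dimensionless per-sample
  multiplier at the post-decimation rate.
* **Normalization** (`normalize_trace`, default `baseline-robust-max`):
  division by the 95th percentile of the baseline-window trace, so the
  prominence threshold 0.2 reads as 20% of a typical baseline burst peak
  and detection is invariant to amplitude scaling. The published threshold's
  units are unstated; the mode is configurable (`zscore`, `none`). A caveat
  discovered with the simulator: when bursts occupy less than ~5% of the
  baseline window (e.g. heavy dropout), the 95th percentile lands on the
  noise pedestal rather than on burst flanks, and pedestal wiggles can
  clear the prominence threshold. The remedy is the screening step below,
  not a silent change of normalization.
* **Detection** (`detect_bursts`, default prominence 0.2, distance 15 s):
  local maxima with topographic prominence (height above the higher of the
  two bracketing minima separating the peak from larger peaks) at least the
  threshold; among peaks closer than the minimum distance the higher wins,
  ties to the earlier. Onset/offset are the nearest linear-interpolated
  crossings of `peak - prominence/2`, giving a half-prominence width —
  the published analysis does not define width, and this definition is
  robust to baseline drift (alternatives are configurable). Height is the
  trace maximum within the burst; area is the within-burst Riemann sum of
  the conditioned trace divided by the rate.
* **Screening** (`screen_bursts` + `drop_rejected`): the auditable stand-in
  for manual false-positive checking. Bursts outside plausibility bands are
  flagged, never silently removed; exclusion happens only through the
  explicit `drop_rejected` step, which also recomputes periods. The
  analysis scripts use an adaptive height band (a quarter of the median
  detected height) that cleanly separates noise-pedestal peaks from true
  bursts.
* **Epoch analysis** (`assign_epochs`, `summarize_epochs`,
  `normalize_to_baseline`): bursts belong to the epoch whose analysis
  window contains their peak (half-open intervals, t = 0 at the first
  sample). The default protocol is a 10-min baseline analyzed in full and
  20-min drug exposures of which only the final 10 min are analyzed.
  Periods straddling a window boundary are dropped, not prorated — a small,
  logged bias-avoiding choice. Per-epoch means are normalized to the
  slice's baseline means; irregularity is the change in the period CV
  (sample SD over mean; n−1 because per-epoch counts are small). The
  baseline CV uses the full baseline analysis window. Rundown of burst
  height/width is deliberately not detrended: the comparison design is
  time-matched controls, so summaries report raw means.

## Multimodality inference

`dip_statistic` computes Hartigan's dip — the smallest sup-norm distance
between the empirical CDF and the class of unimodal CDFs (convex up to the
mode, concave after, a jump permitted only at the mode) — *exactly*. For
each candidate modal position (every data knot, allowing the modal jump, and
every inter-knot gap) feasibility of "some unimodal CDF within distance d"
is decided by propagating the convex polygon of attainable (slope, value)
states of the bounding chain through the ECDF box constraints; the dip is
the bisection minimum of d over all modal positions (64 bisection steps,
i.e. distance resolved to ~1e-19; ties are collapsed into weighted knots).
The test suite checks this implementation against an independent brute
force that solves each modal position as a linear program
(`inst/oracle/dip_oracle.R`, using `boot::simplex`), exactly on samples up
to n = 8, plus known closed-form anchors (two points give 1/4, equal
spacing gives 1/(2n), two half-weight clusters approach 1/4).

`dip_test` calibrates by bootstrap: the p-value is the proportion of
`n_boot` null samples of size n whose dip reaches the observed dip
(default `n_boot` 10,000, seed recorded). Two nulls are offered:

* `"uniform"` — the test's standard calibration and the default. It is the
  asymptotically least-favorable unimodal null and therefore *conservative*
  for peaked samples: the acceptance script measures its empirical type-I
  rate on gamma-distributed periods (CV 0.1, n = 60) alongside every run,
  and it sits near zero rather than near the nominal 5%.
* `"matched"` — a gamma parametric bootstrap, moment-fitted to the sample.
  For burst periods (positive, peaked, CV ~0.1–0.3) this restores honest
  calibration: the acceptance suite requires its type-I rate at alpha 0.05
  to lie in [0.03, 0.07] under the generator's own gamma null, and requires
  rejection under 30% dropout to exceed three times that rate.

Mode locations of multimodal samples are reported by a 1-D Gaussian-mixture
decomposition (`estimate_modes`, unequal variances, component count by BIC
among 1..3, EM via mclust behind the module surface; the ± values are
component SDs since the original report's convention is unstated; a
KDE-peak alternative was considered and rejected as harder to audit).
`burstlet_consistency_check` then asks whether higher modes sit at integer
multiples of the first mode within a 15% relative tolerance — the burstlet
dropout signature — and reports the implied burstlet fraction (weight of
the first mode). Applied to mode pairs like 0.93/1.43 (ratio 1.54) it
reports "inconsistent with pure dropout", the arithmetic behind reading
such a pattern as rhythm-generator modulation rather than transmission
failure.

Outliers are screened beforehand by the two-sided Smirnov–Grubbs test
(`grubbs_exclude`, alpha 0.05): iteratively, the most extreme value is
removed while `max|x - mean|/SD` exceeds the closed-form t-quantile
critical value, recomputed on the reduced sample. The closed form is exact
at any n, unlike table lookups.

## Group inference

`fit_gee` implements Gaussian generalized estimating equations with
identity link, exchangeable (default) or independence working correlation,
a moment estimator for the exchangeable correlation, and the cluster-robust
sandwich covariance; convergence is declared at 1e-8 on the max coefficient
change (at most 100 iterations, error carrying the last iterate
otherwise). GEE is used instead of ANOVA because drug conditions change the
response variance across groups (variance homogeneity fails); the working
correlation choice is a sensitivity knob, not auto-selected. With singleton
clusters and independence the fit reduces exactly to OLS — a degeneracy the
tests exploit, cross-checking the sandwich against an independent
clustered-covariance implementation. `bonferroni_contrasts` forms Wald
z-tests of condition differences on robust SEs with `min(1, k p)`
adjustment. For interval estimation with few clusters, `confint` uses
Student-t critical values with `clusters - p` degrees of freedom, the usual
small-cluster convention — plain z intervals measurably undercover at 12
clusters. Mancl–DeRouen-style small-sample SE corrections are a documented
non-goal. The model formula is response ~ condition only; epoch order and
other covariates are not modeled.

## The receptor-occupancy dose model

PGE2 binds six prostanoid receptors with very different affinities (Kd in
nM: EP3 0.33, EP4 0.59, EP2 13, EP1 25, FP 119, DP2 307). The mechanistic
mode maps single-site occupancies `theta = c/(c + Kd)` to a burst-period
multiplier

    m(c) = 1 + a3 * theta_EP3(c) - a2 * theta_EP2(c),   floored at 0.1,

the simplest form consistent with EP3 activation slowing and EP2 activation
accelerating the rhythm. The gains are calibrated by solving the 2×2 linear
system through two anchor effects (+21% at 1 nM, −24% at 1 uM), giving
a2 ≈ 0.582, a3 ≈ 0.335. Because EP3's affinity is ~40× EP2's, m rises
above 1 at low concentrations and falls below 1 at high ones, crossing 1
exactly once — the biphasic profile. Two deliberate model notes: (i) a
one-site model with these affinities cannot reach the +25% observed at
10 nM (it yields about +7% there); the shortfall is retained as a
falsifiable residual rather than absorbed by extra parameters, since
whether the 10 nM excess reflects cooperativity or network amplification is
an open question. (ii) Antagonists are modeled as full receptor block
(occupancy forced to zero), appropriate for antagonists applied at
saturating multiples of their potency; a competitive-shift mode is an
extension hook. EP4, FP and DP2 occupancies are computed but carry zero
gain by default, matching the finding that their blockade leaves the
biphasic response intact; blocking EP2 and EP3 together abolishes the
response entirely. The empirical mode bypasses mechanism and
log-linearly interpolates anchor multipliers (1 nM → 1.21, 10 nM → 1.25,
1 uM → 0.76), constant beyond the anchored range; the simulator uses it by
default so that the 10 nM condition carries its full published effect.

## The synthetic generator

`synthesize_recording` emulates: gamma-distributed burstlet intervals
(positivity plus direct CV parameterization; the interval law itself is a
modeling choice, not an observed quantity) whose mean is the baseline
period times the epoch's dose multiplier; Bernoulli transmission dropout;
a double-exponential burst kernel (rise 0.05 s, decay 0.3 s, peak-aligned
to the event time) scaled by a compounding rundown of 1%/min; and white
Gaussian noise (SD 0.05 of the unit peak). Defaults are the study
conditions. The baseline period default is 25 s (0.04 Hz): a slice rhythm
analyzed with a 15 s minimum peak distance must be slower than ~0.05 Hz to
be observable at all, so faster defaults would be inconsistent with the
detection parameters the analysis itself uses; 25 s also keeps the 1 uM
arm (multiplier 0.76 → 19 s) clear of the distance rule. Interval CV 0.10
and between-slice lognormal spread (sdlog 0.2 in the experiment battery)
are chosen as typical of such preparations. Dose multipliers scale only
the mean interval; an explicit per-epoch `cv_scale` knob emulates the
irregularity increase at 10 nM (scale 1.6 turns baseline CV 0.10 into
0.16, i.e. the +0.06 CV change).

What the generator does *not* emulate — and hence what green tests do not
certify about real data: burst-shape variability and within-burst
structure, slow baseline drift and electrode artifacts beyond isolated
spikes, non-renewal dependence between consecutive intervals (e.g.
post-sigh resets), amplitude-period coupling, and any biophysics of the
preBötC network. It provides the statistical phenomenology the analysis
assumes, no more.

All generator randomness flows from a single integer seed
(`set.seed` at entry; identical seed, identical output). Sub-experiments
derive distinct sub-seeds deterministically.

## Problem sizes and numerical choices

The acceptance suite and script run, per invocation: 200 random samples
(n ≤ 8) against the LP oracle; dip calibration with a shared 2,000-draw
null table and 1,000 replicate samples of 60 periods; 20 (tests) or 10
(script) end-to-end recovery recordings per dose arm; 50 detection-fidelity
recordings of ~510 s; 500 GEE replicates at 12 clusters × 2 observations.
The end-to-end recovery experiment stretches the protocol windows threefold
(30 min baseline, 60 min exposure, last 30 analyzed): at a 25 s rhythm the
wet-lab 10-min windows hold only ~25 periods, whose sampling noise (about
±3.5% SE on a period ratio) would dominate a ±5% recovery band; the
stretched windows restore the period count such a band presumes, without
touching the generator's rhythm parameters.

Numerical details worth knowing: the dip bisection tolerance (1e-14 on d)
is far below the 1e-10 oracle-agreement tolerance; polygon clipping uses a
1e-12 feasibility slack; Hampel windows at the edges shrink rather than
pad; decimation keeps the first sample of each block, so a factor-1 call
is the identity; the leaky integrator is `stats::filter(..., recursive)`
with zero initial state, so the impulse response is exactly `0.98^n`;
detection interpolates onset/offset linearly between samples, making the
triangle-pulse width exact; detected peak times lag the true event times by
a constant ~0.2 s (the integrator's group delay), well inside the ±0.25 s
matching tolerance and irrelevant to periods, which difference it away.

## Known limitations

* The dip test's uniform null is conservative for peaked period samples;
  use the matched null for calibrated per-slice inference and interpret
  uniform-null non-rejections accordingly.
* Mixture-based mode decomposition needs tens of periods per component;
  with ~25 periods per epoch the per-epoch dip test has limited power
  (pooling periods across epochs after median normalization, as the
  multimodality analysis script does, mitigates this).
* The sandwich covariance is anti-conservative below ~10 clusters even
  with t intervals.
* The mechanistic receptor model is deliberately minimal: one site per
  receptor, linear occupancy-to-period mapping, full-block antagonism.
* Trace units are treated as arbitrary throughout; no gain correction is
  attempted, and all effect sizes are baseline-relative.
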