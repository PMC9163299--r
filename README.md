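# xiirhythm

Burst-rhythm analysis of hypoglossal (XII) nerve rootlet recordings from
rhythmic brainstem slice preparations, with a burstlet-train simulator that
provides ground truth for every stage.

Slices containing the preBötzinger complex produce inspiratory-like bursts
on the XII rootlets. Drugs such as prostaglandin E2 (PGE2) change the burst
period biphasically — lengthening it at nanomolar concentrations, shortening
it at micromolar ones — and may change its regularity. `xiirhythm` is for
electrophysiologists and analysts who need to turn such raw extracellular
traces into per-condition burst statistics and defensible inference:

* **Conditioning**: decimation (1/10), Hampel artifact replacement (0.5 s
  window, 5 sigma), rectified leaky integration
  (`y[n] = 0.98 y[n-1] + |x[n]|`).
* **Burst detection**: peaks of topographic prominence ≥ 0.2 on the
  baseline-normalized integrated trace, minimum distance 15 s; onset/offset
  at half prominence; auditable flag-and-review screening instead of silent
  manual edits.
* **Epoch statistics**: per-burst period, height, width and area, averaged
  per epoch (10-min baseline, last 10 min of each 20-min exposure) and
  normalized to baseline; period irregularity as the change in the
  coefficient of variation.
* **Multimodality inference**: Smirnov–Grubbs outlier screening, an exact
  implementation of Hartigan's dip statistic with seeded bootstrap
  calibration (uniform or matched-gamma null), Gaussian-mixture mode
  decomposition, and a burstlet-dropout consistency check — modes of a
  multimodal period distribution should sit at integer multiples of the
  burstlet period,

      T_k ≈ k · T_burstlet,   weight(T_1)/Σweights = burstlet fraction.

* **Group inference**: Gaussian GEE (exchangeable or independence working
  correlation, sandwich covariance) with Bonferroni-adjusted contrasts, for
  repeated-measures designs where variance homogeneity fails.
* **Receptor dose-response model**: single-site occupancies
  θ = c/(c + Kd) over the prostanoid panel (EP3 0.33 nM, EP4 0.59, EP2 13,
  EP1 25, FP 119, DP2 307) drive a period multiplier
  m(c) = 1 + a₃·θ_EP3 − a₂·θ_EP2, calibrated to +21% at 1 nM and −24% at
  1 µM, reproducing the biphasic profile and antagonist predictions.
* **Synthetic recordings**: gamma burstlet trains with transmission dropout,
  double-exponential burst kernels, amplitude rundown and noise — the
  statistical structure the analysis assumes, with full ground truth.

## Worked example

Simulate a slice exposed to 10 nM PGE2 (dose multiplier 1.25 on the burst
period) and run the full pipeline:

```r
library(xiirhythm)
plan <- default_epoch_plan("PGE2_10nM", 30, 60, 30)   # minutes
cfg  <- synth_config(seed = 42, epoch_plan = plan)
sim  <- synthesize_recording(cfg)
res  <- run_pipeline(sim$rec, plan)
res$summary[, c("epoch_label", "n_bursts", "mean_period_s",
                "normalized_period", "delta_cv")]
#>   epoch_label n_bursts mean_period_s normalized_period delta_cv
#> 1    baseline       71         25.07             1.000 0.000000
#> 2   PGE2_10nM       58         31.43             1.254 0.001195
```

The detected normalized period (1.254) recovers the simulated +25% effect;
`delta_cv ≈ 0` because this configuration did not perturb the rhythm's
jitter. Now the burstlet-theory readout — periods from a generator whose
bursts fail to transmit 20% of the time:

```r
per <- generate_period_sample(
  synth_config(seed = 7, dropout_p = 0.2, jitter_cv = 0.05), 120)$periods
dip_test(per, n_boot = 2000, seed = 1, null = "matched")
#> Hartigan dip test: n = 120, dip = 0.0760, p = 0 (matched null, 2000 boots)
m <- estimate_modes(per)
m
#> Mixture decomposition: 2 component(s)
#>   mode 1: 25.214 +/- 1.157 (weight 0.76)
#>   mode 2: 56.989 +/- 18.754 (weight 0.24)
burstlet_consistency_check(m)
#> Burstlet-dropout consistency: higher modes sit at integer multiples of
#> the base period: consistent with burstlet dropout
#>   ratios to first mode: 2.260 (burstlet fraction 0.76)
```

Unimodality is rejected, the second mode sits near twice the base period,
and the implied burstlet fraction (0.76) is close to the simulated
transmission probability (0.8). A unimodal result with shifted mean would
instead indicate rhythm-generator modulation.

## Analysis workflow

Numbered drivers under `analysis/` reproduce the package's study-style
analyses end to end, writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | synthetic recording battery (clean + dropout slices) |
| `02_detect_bursts.R` | conditioning, detection, plausibility screening |
| `03_epoch_stats.R` | per-epoch summaries normalized to baseline |
| `04_multimodality.R` | Grubbs + dip tests + mode decomposition |
| `05_group_inference.R` | GEE with Bonferroni contrasts on a 12-slice battery |
| `06_dose_response.R` | receptor-occupancy dose-response tables |

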