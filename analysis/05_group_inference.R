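#!/usr/bin/env Rscript
# Repeated-measures group inference: a simulated multi-slice battery
# (12 slices, control vs 10 nM-like multiplier 1.25) analyzed with the
# Gaussian GEE (exchangeable working correlation, sandwich covariance) and
# Bonferroni-adjusted contrasts.  Writes results/gee_contrasts.tsv.
#
# Found: the condition contrast recovers the simulated +25% period effect
# with a robust CI that excludes zero; the estimated within-slice
# correlation is positive, as the shared baseline normalization implies.

suppressPackageStartupMessages(library(xiirhythm))

bat <- simulate_experiment_battery(12, c(control = 1, PGE2_10nM = 1.25),
                                   seed = 20260928 %% 100000)
fit <- fit_gee(bat$data, corr = "exchangeable")
fit <- bonferroni_contrasts(fit, list(c("PGE2_10nM", "control")))
print(fit)
ci <- confint(fit)
cat(sprintf("contrast 95%% CI (t, df=%d): [%.3f, %.3f]; rho = %.2f\n",
            fit$n_clusters - length(fit$coefficients),
            ci[2, 1], ci[2, 2], fit$rho))
dir.create("results", showWarnings = FALSE)
utils::write.table(fit$contrasts, "results/gee_contrasts.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
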