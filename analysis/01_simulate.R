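#!/usr/bin/env Rscript
# Simulate the study's recording battery: one synthetic XII-rootlet trace per
# dose condition (10 nM and 1 uM PGE2 epochs after a baseline), plus a
# dropout variant used by the multimodality analysis.  Writes the traces
# (binary float32 + JSON sidecar), epoch plans and ground truth under
# results/simulated/.
#
# Found: with the default study conditions (25 s baseline period, CV 0.10,
# 1%/min rundown, 5% noise) each 100-min stretched protocol holds ~240
# bursts, and dropout 0.3 thins the transmitted train by ~30%.

suppressPackageStartupMessages(library(xiirhythm))

out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

plan <- default_epoch_plan(c("PGE2_10nM", "PGE2_1000nM"),
                           baseline_min = 20, drug_min = 40,
                           analyzed_min = 20)
write_epoch_plan(plan, file.path(out_dir, "epoch_plan.json"))

for (spec in list(list(id = "slice01", dropout = 0),
                  list(id = "slice02_dropout", dropout = 0.3))) {
  cfg <- synth_config(seed = 100 + nchar(spec$id), dropout_p = spec$dropout,
                      epoch_plan = plan)
  sim <- synthesize_recording(cfg, slice_id = spec$id)
  write_recording(sim$rec, file.path(out_dir, spec$id), format = "binary")
  jsonlite::write_json(sim$ground_truth,
                       file.path(out_dir, paste0(spec$id, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d burstlets, %d transmitted (dropout %.1f)\n", spec$id,
              length(sim$ground_truth$event_times_s),
              length(sim$ground_truth$transmitted_times_s), spec$dropout))
}
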