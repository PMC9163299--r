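test_that("period generation is exact without jitter and reproducible", {
  cfg <- synth_config(seed = 5, jitter_cv = 0, dropout_p = 0)
  g <- generate_period_sample(cfg, 10)
  expect_equal(g$periods, rep(25, 10))
  # dose multiplier scales the mean exactly
  g2 <- generate_period_sample(cfg, 10, "PGE2_10nM")
  expect_equal(g2$periods, rep(25 * 1.25, 10))
  expect_equal(g2$ground_truth$multiplier, 1.25)
  # same seed, same sample
  cfg3 <- synth_config(seed = 7, jitter_cv = 0.1, dropout_p = 0.2)
  a <- generate_period_sample(cfg3, 50)
  b <- generate_period_sample(cfg3, 50)
  expect_identical(a$periods, b$periods)
})

test_that("dropout thins transmission and lengthens apparent periods 1/(1-p)", {
  cfg <- synth_config(seed = 11, jitter_cv = 0.05, dropout_p = 0.3)
  g <- generate_period_sample(cfg, 500)
  gt <- g$ground_truth
  # thinning: observed events ~ (1 - p) of burstlets
  expect_equal(length(gt$transmitted_times_s) / length(gt$event_times_s),
               0.7, tolerance = 0.05)
  expect_true(all(gt$transmitted_times_s %in% gt$event_times_s))
  # renewal argument: mean observed period = base / (1 - p)
  expect_equal(mean(g$periods), 25 / 0.7, tolerance = 0.05 * 25 / 0.7)
  # mass clusters beyond 1.5x base approximate the dropout probability
  expect_equal(mean(g$periods > 1.5 * 25), 0.3, tolerance = 0.05)
})

test_that("synthesized recordings have the configured burst structure", {
  # noiseless single event: trace maximum is peak_amp at the event time
  cfg <- synth_config(seed = 1, noise_sd = 0, rundown_per_min = 0,
                      epoch_plan = epoch_plan("baseline", 0, 60),
                      jitter_cv = 0)
  sim <- synthesize_recording(cfg)
  i <- which.max(sim$rec$samples)
  expect_equal(max(sim$rec$samples), 1, tolerance = 1e-6)
  expect_equal((i - 1) / cfg$rate_hz, sim$ground_truth$transmitted_times_s[1],
               tolerance = 2 / cfg$rate_hz)
  # rundown: detected burst heights trend downward over 30 min
  cfg2 <- synth_config(seed = 2, rundown_per_min = 0.01,
                       epoch_plan = epoch_plan("baseline", 0, 1800))
  sim2 <- synthesize_recording(cfg2)
  nt <- normalize_trace(condition(sim2$rec), "baseline-robust-max", c(0, 1800))
  tab <- detect_bursts(nt, detection_params())
  expect_gt(nrow(tab), 40)
  trend <- coef(lm(height ~ peak_t_s, tab))[2]
  expect_lt(trend, 0)
  # determinism of the full recording
  expect_identical(synthesize_recording(cfg)$rec$samples, sim$rec$samples)
})

test_that("dropout-free period samples look unimodal to the dip test", {
  set.seed(1)
  nulld <- dip_null_sample(60, 400, null = "uniform")
  q95 <- quantile(nulld, 0.95, names = FALSE)
  rej <- sapply(1:30, function(sd) {
    g <- generate_period_sample(synth_config(seed = sd, jitter_cv = 0.1), 60)
    as.numeric(dip_statistic(g$periods)) >= q95
  })
  expect_gte(mean(!rej), 0.9)
})

test_that("the experiment battery emits the group-inference schema", {
  bat <- simulate_experiment_battery(6, c(ctrl = 1, drug = 1.25), seed = 4)
  expect_equal(nrow(bat$data), 12)
  expect_setequal(unique(bat$data$condition), c("ctrl", "drug"))
  expect_true(all(is.finite(bat$data$response)))
  bat2 <- simulate_experiment_battery(6, c(ctrl = 1, drug = 1.25), seed = 4)
  expect_identical(bat$data, bat2$data)
  # recovered contrast has the right sign and rough size
  f <- bonferroni_contrasts(fit_gee(bat$data))
  expect_equal(f$contrasts$estimate, 0.25, tolerance = 0.1)
})
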