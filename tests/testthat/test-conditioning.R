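test_that("decimation reduces rate and length and preserves constants", {
  rec <- recording(rnorm(20), 20000)
  d <- decimate(rec, 10)
  expect_equal(d$rate_hz, 2000)
  expect_equal(length(d$samples), 2L)
  expect_identical(decimate(rec, 1), rec)
  cst <- recording(rep(3.7, 100), 1000)
  expect_equal(decimate(cst, 10)$samples, rep(3.7, 10))
  expect_error(decimate(rec, 21), "exceeds")
  # composing decimations matches a single combined factor in shape
  r2 <- recording(rnorm(1000), 1000)
  a <- decimate(decimate(r2, 2), 5)
  b <- decimate(r2, 10)
  expect_equal(a$rate_hz, b$rate_hz)
  expect_equal(length(a$samples), length(b$samples))
})

test_that("hampel filter matches the naive sliding median/MAD oracle", {
  # constant trace: untouched, nothing flagged
  cst <- recording(rep(1, 50), 100)
  hc <- hampel_filter(cst, 0.1, 5)
  expect_equal(hc$rec$samples, rep(1, 50))
  expect_length(hc$flagged, 0)
  # lone spike among zeros is replaced by the window median (0)
  spk <- recording(c(rep(0, 10), 100, rep(0, 10)), 100)
  hs <- hampel_filter(spk, 0.1, 5)
  expect_equal(hs$flagged, 11L)
  expect_equal(hs$rec$samples[11], 0)
  # random walk with injected artifacts: index-by-index oracle agreement
  set.seed(42)
  x <- cumsum(rnorm(400))
  x[c(50, 51, 200, 333)] <- x[c(50, 51, 200, 333)] + c(40, -35, 60, 25)
  rec <- recording(x, 100)          # 0.5 s window -> h = 25
  got <- hampel_filter(rec, 0.5, 5)
  want <- hampel_oracle(x, 25, 5)
  expect_equal(got$rec$samples, want$y)
  expect_equal(got$flagged, want$flagged)
  expect_true(all(c(50, 200, 333) %in% got$flagged))
  expect_error(hampel_filter(recording(1:5, 1), 0.5, 5), "fewer than 3")
})

test_that("hampel filtering is idempotent on traces with no artifacts", {
  set.seed(7)
  rec <- recording(sin(seq(0, 20, by = 0.01)) + rnorm(2001, 0, 0.02), 100)
  once <- hampel_filter(rec, 0.3, 5)
  twice <- hampel_filter(once$rec, 0.3, 5)
  expect_length(once$flagged, 0)
  expect_length(twice$flagged, 0)
  expect_equal(twice$rec$samples, once$rec$samples)
})

test_that("leaky integrator matches closed-form impulse and step responses", {
  n <- 400
  imp <- recording(c(1, rep(0, n - 1)), 100)
  yi <- leaky_integrate(imp, 0.98)$samples
  expect_equal(yi, 0.98^(0:(n - 1)), tolerance = 1e-9)
  stp <- recording(rep(1, 2000), 100)
  ys <- leaky_integrate(stp, 0.98)$samples
  # geometric series: steady state 1 / (1 - 0.98) = 50
  expect_equal(ys[2000], 50 * (1 - 0.98^2000), tolerance = 1e-9)
  expect_lt(abs(ys[2000] - 50), 1e-9)
  # positive homogeneity
  set.seed(1)
  x <- rnorm(200)
  expect_equal(leaky_integrate(recording(3 * x, 10), 0.9)$samples,
               3 * leaky_integrate(recording(x, 10), 0.9)$samples)
  expect_error(leaky_integrate(imp, 1), "in \\(0, 1\\)")
})

test_that("condition() is the stage-by-stage composition and preserves bursts", {
  set.seed(3)
  cfg <- synth_config(seed = 3, rate_hz = 2000,
                      epoch_plan = epoch_plan("baseline", 0, 300))
  sim <- synthesize_recording(cfg)
  pars <- conditioning_params()
  got <- condition(sim$rec, pars)
  manual <- leaky_integrate(
    hampel_filter(decimate(sim$rec, 10), 0.5, 5)$rec, 0.98)
  expect_equal(got$samples, manual$samples)
  expect_equal(got$rate_hz, 200)
  # constant input settles at c / (1 - decay)
  cst <- condition(recording(rep(2, 50000), 2000), pars)
  expect_equal(tail(cst$samples, 1), 2 / (1 - 0.98), tolerance = 1e-6)
  # burst count preserved through conditioning
  nt <- normalize_trace(got, "baseline-robust-max", c(0, 300))
  tab <- detect_bursts(nt, detection_params())
  expect_equal(nrow(tab), length(sim$ground_truth$transmitted_times_s))
})
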