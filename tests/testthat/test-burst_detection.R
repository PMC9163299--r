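test_that("a single bump is detected once, at its center", {
  rec <- bump_trace(10, rate = 100, dur = 20)
  tab <- detect_bursts(rec, detection_params(min_prominence = 0.5))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$peak_t_s, 10, tolerance = 0.02)
  expect_equal(tab$height, 1, tolerance = 1e-3)
})

test_that("the min-distance rule keeps the higher peak, ties to the earlier", {
  # two identical bumps 10 s apart with 15 s minimum distance -> 1 burst
  rec <- bump_trace(c(10, 20), rate = 100, dur = 35)
  tab <- detect_bursts(rec, detection_params(min_prominence = 0.3,
                                             min_distance_s = 15))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$peak_t_s, 10, tolerance = 0.1)  # earlier wins the tie
  # higher second bump wins instead
  t <- seq(0, 35, by = 0.01)
  x <- exp(-(t - 10)^2 / 0.5) + 1.5 * exp(-(t - 20)^2 / 0.5)
  tab2 <- detect_bursts(recording(x, 100),
                        detection_params(min_prominence = 0.3,
                                         min_distance_s = 15))
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$peak_t_s, 20, tolerance = 0.1)
})

test_that("empty or flat traces yield an empty table, not an error", {
  expect_equal(nrow(detect_bursts(recording(rep(0.5, 1000), 100),
                                  detection_params())), 0L)
  expect_equal(nrow(detect_bursts(recording(c(1, 2), 100),
                                  detection_params())), 0L)
})

test_that("triangle and rectangle pulses give the textbook features", {
  # symmetric triangle, base 2 s, apex 1.0 on a flat 0 baseline
  rate <- 1000
  t <- seq(0, 20, by = 1 / rate)
  x <- pmax(0, 1 - abs(t - 10))
  tab <- detect_bursts(recording(x, rate),
                       detection_params(min_prominence = 0.5))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$height, 1.0, tolerance = 1e-6)
  # half-prominence crossings at apex +/- 0.5 -> width 1 s
  expect_equal(tab$width_s, 1.0, tolerance = 2 / rate)
  # area between the crossings: trapezoid (1 + 0.5)/2 * 1 = 0.75
  expect_equal(tab$area, 0.75, tolerance = 2e-3)
  # rectangle height h width w: height h, area ~ h * w
  xr <- ifelse(t >= 9 & t < 12, 2, 0)
  tr <- detect_bursts(recording(xr, rate), detection_params(min_prominence = 1))
  expect_equal(tr$height, 2)
  expect_equal(tr$width_s, 3, tolerance = 3 / rate)
  expect_equal(tr$area, 6, tolerance = 2 * 2 / rate)
})

test_that("detection is time-shift equivariant and scale invariant", {
  set.seed(11)
  times <- c(8, 26, 47, 66, 85)
  rec <- bump_trace(times, rate = 50, dur = 100, noise = 0.02)
  par <- detection_params(min_prominence = 0.2, min_distance_s = 15)
  base <- detect_bursts(rec, par)
  # shift by an integer number of samples
  shift_n <- 50 * 4  # 4 s
  shifted <- recording(c(rep(rec$samples[1], shift_n), rec$samples), 50)
  tabs <- detect_bursts(shifted, par)
  expect_equal(tabs$peak_t_s, base$peak_t_s + 4)
  expect_equal(tabs$height, base$height)
  # amplitude scaling cancels under baseline-robust-max normalization
  par2 <- detection_params(min_prominence = 0.2)
  n1 <- normalize_trace(rec, "baseline-robust-max", c(0, 100))
  r3 <- recording(rec$samples * 37, 50)
  n2 <- normalize_trace(r3, "baseline-robust-max", c(0, 100))
  expect_equal(detect_bursts(n1, par2), detect_bursts(n2, par2))
})

test_that("normalization modes behave as documented", {
  rec <- bump_trace(c(10, 30), rate = 50, dur = 45, amp = 4)
  nb <- normalize_trace(rec, "baseline-robust-max", c(0, 45))
  div <- quantile(rec$samples, 0.95, names = FALSE)
  expect_equal(nb$samples, rec$samples / div)
  expect_identical(normalize_trace(rec, "none"), rec)
  expect_error(normalize_trace(recording(rep(0, 100), 10),
                               "baseline-robust-max", c(0, 5)), "positive")
  expect_error(normalize_trace(rec, "baseline-robust-max"), "required")
})

test_that("every reported period equals the difference of adjacent peaks", {
  set.seed(2)
  cfg <- synth_config(seed = 2, epoch_plan = epoch_plan("baseline", 0, 500))
  sim <- synthesize_recording(cfg)
  nt <- normalize_trace(condition(sim$rec), "baseline-robust-max", c(0, 500))
  tab <- detect_bursts(nt, detection_params())
  expect_gt(nrow(tab), 10)
  expect_equal(tab$period_to_next_s[-nrow(tab)], diff(tab$peak_t_s))
  expect_true(is.na(tab$period_to_next_s[nrow(tab)]))
  expect_true(all(diff(tab$peak_t_s) >= 15))
})

test_that("screening flags implausible bursts without removing them", {
  tab <- burst_features(
    recording(pmax(0, 1 - abs(seq(0, 20, 0.01) - 10)), 100),
    detect_bursts(recording(pmax(0, 1 - abs(seq(0, 20, 0.01) - 10)), 100),
                  detection_params(min_prominence = 0.5)))
  scr <- screen_bursts(tab, width_band = c(2, 5))  # width 1 s -> flagged
  expect_true(all(scr$flag))
  expect_equal(nrow(scr), nrow(tab))  # still present
  ok <- screen_bursts(tab, width_band = c(0.1, 5))
  expect_false(any(ok$flag))
  expect_equal(nrow(attr(ok, "review")), 0L)
})
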