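mk_tab <- function(peaks, slice = "s1") {
  tab <- xiirhythm:::burst_table_empty()
  tab <- tab[rep(1, 0), ]
  n <- length(peaks)
  out <- data.frame(slice_id = slice, epoch_label = NA_character_,
                    peak_t_s = peaks, onset_t_s = peaks - 0.5,
                    offset_t_s = peaks + 0.5, height = 1, width_s = 1,
                    area = 0.5, period_to_next_s = c(diff(peaks), NA),
                    flag = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("burst_table", "data.frame")
  out
}

test_that("bursts land in the epoch whose analysis window contains their peak", {
  plan <- default_epoch_plan("drug")
  tab <- mk_tab(c(100, 900, 1300, 1795))
  got <- suppressMessages(assign_epochs(tab, plan))
  expect_equal(got$epoch_label, c("baseline", NA, "drug", "drug"))
  expect_equal(attr(got, "n_unassigned"), 1L)
  # partition: assigned + unassigned = total
  expect_equal(sum(!is.na(got$epoch_label)) + attr(got, "n_unassigned"),
               nrow(tab))
})

test_that("periods straddling a window boundary are dropped", {
  plan <- default_epoch_plan("drug")
  tab <- mk_tab(c(1195, 1210, 1230))
  got <- suppressMessages(assign_epochs(tab, plan))
  # burst at 1195 is before the drug analysis window (1200): its period to
  # 1210 must not survive
  expect_true(is.na(got$period_to_next_s[1]))
  expect_equal(got$period_to_next_s[2], 20)
})

test_that("epoch summaries compute the documented statistics", {
  tab <- mk_tab(c(0, 2, 4, 6, 8))
  s <- summarize_epoch(tab)
  expect_equal(s$mean_period_s, 2)
  expect_equal(s$cv_period, 0)
  tab2 <- mk_tab(c(0, 1, 4))  # periods 1 and 3
  s2 <- summarize_epoch(tab2)
  expect_equal(s2$mean_period_s, 2)
  expect_equal(s2$cv_period, sqrt(2) / 2)  # sample SD sqrt(2) over mean 2
  tab3 <- mk_tab(c(0, 1, 4))
  tab3$height <- c(1, 2, 3)
  expect_equal(summarize_epoch(tab3)$mean_height, 2)
  # a single burst has no period statistics
  s1 <- summarize_epoch(mk_tab(5))
  expect_true(is.na(s1$mean_period_s) && is.na(s1$cv_period))
  expect_equal(s1$n_bursts, 1L)
})

test_that("baseline normalization gives ratios and delta-CV", {
  su <- data.frame(
    slice_id = "s1", epoch_label = c("baseline", "drug"),
    n_bursts = c(20, 20),
    mean_period_s = c(2.0, 2.5), mean_height = c(4, 2), mean_width_s = c(1, 1),
    mean_area = c(2, 1), cv_period = c(0.10, 0.16))
  class(su) <- c("epoch_summary", "data.frame")
  got <- normalize_to_baseline(su)
  expect_equal(got$normalized_period, c(1, 1.25))
  expect_equal(got$normalized_height, c(1, 0.5))
  expect_equal(got$delta_cv, c(0, 0.06))
  # identity epoch
  expect_equal(got$normalized_period[got$epoch_label == "baseline"], 1)
  # zero baseline mean is an error
  su2 <- su; su2$mean_area[1] <- 0
  expect_error(normalize_to_baseline(su2), "baseline mean")
})

test_that("normalization is invariant to rescaling a slice's raw features", {
  su <- data.frame(
    slice_id = "s1", epoch_label = c("baseline", "d1", "d2"),
    n_bursts = 30,
    mean_period_s = c(2, 2.4, 1.6), mean_height = c(3, 2.7, 2.2),
    mean_width_s = c(1, 1.1, 0.9), mean_area = c(2, 1.9, 1.4),
    cv_period = c(0.1, 0.12, 0.2))
  class(su) <- c("epoch_summary", "data.frame")
  a <- normalize_to_baseline(su)
  su2 <- su
  for (v in c("mean_period_s", "mean_height", "mean_width_s", "mean_area"))
    su2[[v]] <- su2[[v]] * 7.3
  b <- normalize_to_baseline(su2)
  for (v in c("normalized_period", "normalized_height", "normalized_width",
              "normalized_area"))
    expect_equal(b[[v]], a[[v]])
  # CV itself is scale free: periods scaled by a > 0 leave cv unchanged
  per <- c(1.8, 2.2, 2.0, 2.4)
  s1 <- summarize_epoch(mk_tab(cumsum(c(0, per))))
  s2 <- summarize_epoch(mk_tab(cumsum(c(0, per * 3))))
  expect_equal(s1$cv_period, s2$cv_period)
})
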