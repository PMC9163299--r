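test_that("grubbs exclusion removes the planted outlier and stops", {
  x <- c(1.0, 1.1, 0.9, 1.05, 0.95, 8.0)
  g <- grubbs_exclude(x, 0.05)
  expect_equal(g$excluded_indices, 6L)
  expect_equal(sort(g$kept), sort(x[-6]))
  # oracle: closed-form critical value comparison, round 1
  n <- 6
  tq <- qt(0.05 / (2 * n), n - 2, lower.tail = FALSE)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  expect_gt(g$g_statistics[1], gcrit)
  # excluded value is always the max deviation from the mean
  set.seed(4)
  for (i in 1:20) {
    y <- rnorm(15)
    gy <- grubbs_exclude(y, 0.2)
    if (length(gy$excluded_indices)) {
      first <- gy$excluded_indices[1]
      expect_equal(first, which.max(abs(y - mean(y))))
    }
  }
})

test_that("grubbs handles degenerate samples and alpha monotonicity", {
  expect_length(grubbs_exclude(rep(1, 5))$excluded_indices, 0)
  expect_warning(g2 <- grubbs_exclude(c(1, 2)), "n >= 3")
  expect_length(g2$excluded_indices, 0)
  set.seed(8)
  y <- c(rnorm(20), 6, -5.5)
  n_ex <- sapply(c(0.01, 0.05, 0.10, 0.20),
                 function(a) length(grubbs_exclude(y, a)$excluded_indices))
  expect_true(all(diff(n_ex) >= 0))  # monotone non-decreasing in alpha
})

test_that("dip statistic equals the brute-force LP oracle on small samples", {
  skip_if_not_installed("boot")
  set.seed(123)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    x <- if (i %% 3 == 0) round(runif(n, 0, 2), 1) else rnorm(n)
    expect_equal(as.numeric(dip_statistic(x)), dip_oracle(x),
                 tolerance = 1e-10)
  }
})

test_that("dip statistic hits its known anchors and invariances", {
  expect_equal(as.numeric(dip_statistic(c(0, 1))), 0.25)
  expect_equal(as.numeric(dip_statistic(0:9)), 1 / 20)
  expect_equal(as.numeric(dip_statistic(c(0, 1, 9, 10))), 2 / 9)
  # two tight clusters: dip approaches the 1/4 upper bound
  set.seed(5)
  x2 <- c(rnorm(50, 0, 1e-6), rnorm(50, 1, 1e-6))
  expect_equal(as.numeric(dip_statistic(x2)), 0.25, tolerance = 1e-3)
  # bounds and affine invariance over random samples
  for (i in 1:30) {
    n <- sample(2:80, 1)
    x <- rnorm(n)
    d <- as.numeric(dip_statistic(x))
    expect_gte(d, 1 / (2 * n) - 1e-12)
    expect_lte(d, 0.25 + 1e-12)
    expect_equal(as.numeric(dip_statistic(-2.5 * x + 3)), d,
                 tolerance = 1e-10)
  }
  expect_error(dip_statistic(1), "n >= 2")
})

test_that("dip test is deterministic given a seed and reports its pieces", {
  set.seed(31)
  x <- rgamma(50, 30, 3)
  a <- dip_test(x, n_boot = 300, seed = 99)
  b <- dip_test(x, n_boot = 300, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$n, 50)
  expect_equal(a$seed, 99)
  expect_true(a$p_value >= 0 && a$p_value <= 1)
  # strongly bimodal data are rejected even by the conservative uniform null
  xb <- c(rnorm(40, 0, 0.05), rnorm(40, 1, 0.05))
  expect_lt(dip_test(xb, n_boot = 300, seed = 1)$p_value, 0.01)
  # matched gamma null on gamma data gives a non-extreme p
  pm <- dip_test(x, n_boot = 300, seed = 2, null = "matched")$p_value
  expect_gt(pm, 0.05)
})

test_that("mixture decomposition recovers planted modes and degenerates safely", {
  set.seed(9)
  x <- c(rnorm(140, 1, 0.05), rnorm(60, 2, 0.1))
  m <- estimate_modes(x, seed = 1)
  expect_equal(m$n_components, 2L)
  expect_equal(m$modes$mean, c(1, 2), tolerance = 0.05)
  expect_equal(m$modes$weight, c(0.7, 0.3), tolerance = 0.1)
  # single gaussian -> 1 component by BIC
  set.seed(10)
  m1 <- estimate_modes(rnorm(200, 1, 0.1), seed = 1)
  expect_equal(m1$n_components, 1L)
  # all-equal sample falls back to one degenerate component
  md <- estimate_modes(rep(2, 10), seed = 1)
  expect_equal(md$n_components, 1L)
  expect_equal(md$modes$mean, 2)
})

test_that("burstlet consistency check separates dropout from rhythm change", {
  mk <- function(means, w = NULL) {
    w <- w %||% rep(1 / length(means), length(means))
    structure(list(modes = data.frame(mean = means, sd = 0.1, weight = w),
                   n_components = length(means)),
              class = "mode_estimate")
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  r2 <- burstlet_consistency_check(mk(c(1, 2), c(0.7, 0.3)))
  expect_true(r2$consistent_with_dropout)
  expect_equal(r2$burstlet_fraction, 0.7)
  # the observed mode pair 0.93 / 1.43 (ratio 1.54) is NOT a multiple
  rp <- burstlet_consistency_check(mk(c(0.93, 1.43)))
  expect_false(rp$consistent_with_dropout)
  expect_equal(rp$ratios, 1.43 / 0.93, tolerance = 1e-12)
  r1 <- burstlet_consistency_check(mk(1))
  expect_match(r1$message, "no dropout signature")
})
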