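test_that("prevalence per 10,000 reproduces the published arithmetic", {
  expect_equal(prevalence_per_10000(477, 9727)$per_10000, 490L)
  expect_equal(prevalence_per_10000(0, 9727)$per_10000, 0L)
  expect_equal(prevalence_per_10000(24, 9727)$per_10000, 25L)
  expect_equal(prevalence_per_10000(83, 9727)$per_10000, 85L)
  expect_equal(prevalence_per_10000(47, 9727)$per_10000, 48L)
  expect_equal(prevalence_per_10000(394, 9727)$per_10000, 405L)
})

test_that("rates under the disclosure floor are published as zero", {
  p <- prevalence_per_10000(3, 9727)      # 3.08 per 10,000 < 5
  expect_equal(p$per_10000, 0L)
  expect_true(p$suppressed)
  p <- prevalence_per_10000(5, 9727)      # 5.14 >= floor
  expect_equal(p$per_10000, 5L)
  expect_false(p$suppressed)
  expect_false(prevalence_per_10000(0, 9727)$suppressed)
  expect_error(prevalence_per_10000(1, 0), "positive")
  expect_error(prevalence_per_10000(5, 4), "numerator")
})

test_that("prevalence is monotone in the numerator", {
  p <- prevalence_per_10000(0:500, 9727, suppression_floor = 0)$per_10000
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 10000))
})

test_that("chi-square reproduces the published education and sex tests", {
  edu <- pearson_chi2(rbind(c(182, 212), c(48, 34)))
  expect_equal(round_half_up(edu$statistic, 1), 4.1)
  expect_equal(round_half_up(edu$p_value, 2), 0.04)
  expect_equal(edu$df, 1)

  sex <- pearson_chi2(rbind(c(114, 280), c(29, 54)))
  expect_equal(round_half_up(sex$statistic, 1), 1.2)
  expect_equal(round_half_up(sex$p_value, 2), 0.28)

  flat <- pearson_chi2(rbind(c(10, 10), c(20, 20)))
  expect_equal(flat$statistic, 0)
  expect_error(pearson_chi2(rbind(c(0, 0), c(5, 5))), "margin")
  expect_error(pearson_chi2(matrix(5, 1, 2)), "2x2")
})

test_that("chi-square matches the double-loop oracle to 1e-9", {
  set.seed(42)
  for (i in 1:25) {
    r <- sample(2:4, 1)
    c <- sample(2:5, 1)
    tab <- matrix(sample(1:80, r * c, replace = TRUE), r, c)
    got <- pearson_chi2(tab)
    expect_equal(got$statistic, oracle_chi2(tab), tolerance = 1e-9)
    expect_equal(got$df, (r - 1) * (c - 1))
    # invariance to permuting rows/columns; scaling cells scales the stat
    expect_equal(pearson_chi2(tab[rev(seq_len(r)), ])$statistic,
                 got$statistic)
    expect_equal(pearson_chi2(tab[, rev(seq_len(c))])$statistic,
                 got$statistic)
    expect_equal(pearson_chi2(3 * tab)$statistic, 3 * got$statistic,
                 tolerance = 1e-9)
  }
})

test_that("t statistics agree with the closed-form oracles", {
  # summary-statistic route
  pooled <- two_sample_t(c(mean = 27.4, sd = 5.7, n = 394),
                         c(mean = 29.4, sd = 7.1, n = 83), "pooled")
  expect_equal(pooled$statistic,
               oracle_t_pooled(27.4, 5.7, 394, 29.4, 7.1, 83),
               tolerance = 1e-12)
  expect_equal(pooled$statistic, -2.7761, tolerance = 1e-4)
  expect_equal(pooled$df, 475)

  welch <- two_sample_t(c(mean = 34.8, sd = 14.3, n = 394),
                        c(mean = 24.9, sd = 20.8, n = 83), "welch")
  expect_equal(welch$statistic,
               oracle_t_welch(34.8, 14.3, 394, 24.9, 20.8, 83),
               tolerance = 1e-12)

  # raw-sample route agrees with its own summaries
  set.seed(9)
  a <- rnorm(60, 10, 2)
  b <- rnorm(40, 11, 2)
  raw <- two_sample_t(a, b, "pooled")
  summ <- two_sample_t(c(mean = mean(a), sd = sd(a), n = 60),
                       c(mean = mean(b), sd = sd(b), n = 40), "pooled")
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
})

test_that("identical groups give t = 0, p = 1", {
  x <- c(mean = 5, sd = 1.3, n = 50)
  for (variant in c("pooled", "welch")) {
    res <- two_sample_t(x, x, variant)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
  }
  expect_error(two_sample_t(c(mean = 1, sd = 1, n = 1), x), "n >= 2")
  expect_error(two_sample_t(c(mean = 1, sd = 0, n = 9), x), "sd")
})

test_that("pooled and Welch agree under equal variances at large n", {
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(4000, 0, 1)
    b <- rnorm(4000, 0.05, 1)
    tp <- two_sample_t(a, b, "pooled")$statistic
    tw <- two_sample_t(a, b, "welch")$statistic
    expect_equal(tp, tw, tolerance = 1e-3)
  }
})

test_that("half-up rounding matches display conventions", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.45, -0.5), 0), c(1, 2, 2, -1))
  expect_equal(round_half_up(24.67, 0), 25)
  expect_equal(round_half_up(36.17, 1), 36.2)
})
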