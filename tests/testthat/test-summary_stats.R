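test_that("descriptive statistics match hand-computed oracles", {
  s <- summarize_conc(c(1, 2, 3, 4))
  expect_equal(s$n, 4)
  expect_equal(s$median, 2.5)  # midpoint of the two central order statistics
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sqrt(5 / 3))  # n - 1 denominator: sqrt(5/3) = 1.2910

  s <- summarize_conc(c(5, 5, 5))
  expect_equal(c(s$min, s$max, s$median, s$mean, s$sd), c(5, 5, 5, 5, 0))

  expect_error(summarize_conc(numeric()), "empty")
  expect_error(summarize_conc(c(-1, 2)), "non-negative")
})

test_that("the survey's nitrate summary reproduces the published table", {
  avg <- seasonal_average(fixture_wells(), "nitrate")
  s <- summarize_conc(avg)
  expect_equal(s$n, 58)
  expect_equal(round_half_away(s$mean), 31.37)
  expect_equal(round_half_away(s$median), 27.48)
  expect_equal(round_half_away(s$sd), 18.87)
  expect_equal(round_half_away(s$min), 1.10)
  expect_equal(round_half_away(s$max), 105.50)
})

test_that("summaries are invariant under permutation of the series", {
  set.seed(42)
  x <- rlnorm(40, 3, 0.5)
  a <- summarize_conc(x)
  b <- summarize_conc(sample(x))
  expect_equal(unclass(a), unclass(b))
})

test_that("report rounding is half away from zero", {
  expect_equal(round_half_away(0.015), 0.02)
  expect_equal(round_half_away(-0.015), -0.02)
  expect_equal(round_half_away(2.675), 2.68)
  expect_equal(round_half_away(c(1.234, 1.235)), c(1.23, 1.24))
})

test_that("exceedance screening uses a strict inequality over wells", {
  w <- fixture_wells()
  ex <- exceedance(w, "nitrate", limit = 50, rule = "average")
  expect_equal(ex$count, 6)  # frozen brute-force count over the averages
  expect_equal(ex$n, 58)
  expect_equal(ex$fraction, 6 / 58)

  expect_equal(exceedance(w, "nitrate", limit = 1000)$count, 0)
  # limit 0: every well with a positive average exceeds
  ex0 <- exceedance(w, "nitrate", limit = 0)
  expect_equal(ex0$count, ex0$n)

  # a well sitting exactly at the limit does not exceed
  tw <- tiny_wells()
  tw$nitrate_spring[1] <- 50; tw$nitrate_autumn[1] <- 50
  expect_equal(exceedance(tw, "nitrate", limit = 50)$count, 1)  # only c=93.25

  # all-ND wells leave the denominator
  expect_equal(exceedance(w, "nitrite", limit = 3)$n, 56)
})

test_that("exceedance fraction is non-increasing in the limit", {
  w <- fixture_wells()
  for (rule in c("average", "any_season")) {
    fr <- vapply(c(0.5, 5, 20, 50, 80, 120), function(L)
      exceedance(w, "nitrate", limit = L, rule = rule)$fraction, numeric(1))
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("any_season exceedance counts wells with either season above", {
  tw <- tiny_wells()  # nitrate spring 48/18.1/123, autumn 42/15.6/63.5
  expect_equal(exceedance(tw, "nitrate", 50, rule = "any_season")$count, 1)
  expect_equal(exceedance(tw, "nitrate", 40, rule = "any_season")$count, 2)
})

test_that("one-sample t test matches its definition and degenerate cases", {
  # mean equal to mu0 gives t = 0, two-sided p = 1
  r <- one_sample_t(c(1, 2, 3, 4, 5), mu0 = 3)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 4)

  # symmetric jitter around mu0
  r <- one_sample_t(c(9, 11, 8, 12), mu0 = 10)
  expect_equal(r$statistic, 0)

  expect_error(one_sample_t(c(2, 2, 2), mu0 = 1), "constant")
  expect_error(one_sample_t(3, mu0 = 1), "at least 2")

  # survey conclusion: nitrate mean significantly below the 50 mg/L standard
  p <- one_sample_t(seasonal_average(fixture_wells(), "nitrate"),
                    mu0 = 50, alternative = "less")
  expect_lt(p$p_value, 0.05)
  expect_true(p$conclusion_at_0p05)
})

test_that("t-test p-value is invariant under a common shift of data and mu0", {
  set.seed(7)
  x <- rlnorm(30, 3, 0.4)
  a <- one_sample_t(x, mu0 = 20)
  b <- one_sample_t(x + 100, mu0 = 120)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)
})

test_that("KS normality check has near-nominal behaviour on known shapes", {
  # size: with estimated parameters the classical KS p-value is conservative,
  # so normal samples should almost never be rejected
  set.seed(11)
  rej <- mean(replicate(200, ks_normality(rnorm(500))$p_value < 0.05))
  expect_lt(rej, 0.05)

  # power: strong lognormality at n = 500 is essentially always detected
  set.seed(12)
  pow <- mean(replicate(50, ks_normality(rlnorm(500, 0, 1.5))$p_value < 0.05))
  expect_gt(pow, 0.95)

  expect_error(ks_normality(c(3, 3, 3, 3, 3)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("KS statistic agrees with the independent Lilliefors implementation", {
  skip_if_not_installed("nortest")
  set.seed(5)
  x <- rlnorm(120, 3, 0.6)
  expect_equal(ks_normality(x)$statistic,
               unname(nortest::lillie.test(x)$statistic))
})

test_that("Pearson correlation handles exact and survey cases", {
  x <- c(1, 2, 4, 8)
  expect_equal(pearson_cor(x, x)$estimate, 1)
  expect_equal(pearson_cor(x, -2 * x + 5)$estimate, -1)
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "at least 3")

  w <- fixture_wells()
  r <- pearson_cor(seasonal_average(w, "nitrate"),
                   seasonal_average(w, "nitrite"))
  expect_equal(r$df, 54)  # 56 complete pairs after the two all-ND wells
  expect_gt(r$p_value, 0.05)  # non-significant, as in the survey
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(9)
  x <- runif(25); y <- runif(25)
  r0 <- pearson_cor(x, y)$estimate
  expect_equal(pearson_cor(3 * x + 1, y)$estimate, r0)
  expect_equal(pearson_cor(x, 0.5 * y + 10)$estimate, r0)
})

test_that("ratio of means is the mean ratio, with a guarded denominator", {
  y <- c(1, 2, 5)
  expect_equal(ratio_of_means(2 * y, y), 2)
  expect_equal(ratio_of_means(c(10, 20), c(1, 2)), 10)
  expect_error(ratio_of_means(c(1, 2), c(0, 0)), "positive mean")

  # the survey-scale ratio is finite and large under exclude
  w <- fixture_wells()
  rr <- ratio_of_means(seasonal_average(w, "nitrate"),
                       seasonal_average(w, "nitrite"))
  expect_true(is.finite(rr) && rr > 1)
})
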