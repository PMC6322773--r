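test_that("percentage error is signed and scale-free", {
  expect_equal(percentage_error(10, 10), 0)
  expect_equal(percentage_error(11, 10), 10)
  expect_equal(percentage_error(8, 10), -20)
  expect_error(percentage_error(5, 0), "positive")
})

test_that("accuracy_summary reproduces hand-computable panels", {
  z <- accuracy_summary(c(0, 0, 0, 0))
  expect_equal(
    unlist(z[c("mpe", "sd", "loa_low", "loa_high", "rmspe", "p10", "p20")]),
    c(mpe = 0, sd = 0, loa_low = 0, loa_high = 0, rmspe = 0,
      p10 = 100, p20 = 100)
  )
  s <- accuracy_summary(c(-10, 10))
  expect_equal(s$mpe, 0)
  expect_equal(s$rmspe, 10) # sqrt((100 + 100)/2)
  expect_equal(s$p10, 100) # threshold is inclusive
  expect_equal(s$p20, 100)
  expect_error(accuracy_summary(5), "at least 2")
})

test_that("accuracy_summary internal identities hold on random samples", {
  set.seed(13)
  for (i in 1:25) {
    pe <- stats::rnorm(200, stats::runif(1, -10, 10), stats::runif(1, 1, 15))
    s <- accuracy_summary(pe)
    expect_equal(s$loa_low, s$mpe - 1.96 * s$sd)
    expect_equal(s$loa_high, s$mpe + 1.96 * s$sd)
    expect_gte(s$rmspe, abs(s$mpe))
    expect_lte(s$p10, s$p20)
    expect_equal(s$n, 200)
  }
})

test_that("summary of large normal errors approaches the analytic values", {
  set.seed(99)
  pe <- stats::rnorm(1e5, 2, 8)
  s <- accuracy_summary(pe)
  expect_equal(s$mpe, 2, tolerance = 0.1)
  expect_equal(s$loa_low, 2 - 1.96 * 8, tolerance = 0.02)
  expect_equal(s$loa_high, 2 + 1.96 * 8, tolerance = 0.02)
  expect_equal(
    s$p10, impute_p_within(2, 2 - 1.96 * 8, 2 + 1.96 * 8, 10),
    tolerance = 0.01
  )
})

test_that("normal-integral imputation matches quadrature and is monotone", {
  # symmetric case against numerical integration of the error density
  quad <- function(mu, sigma, thr) {
    100 * stats::integrate(
      function(x) stats::dnorm(x, mu, sigma), -thr, thr
    )$value
  }
  for (case in list(c(0, 5, 10), c(3, 8, 10), c(-6, 12, 20), c(1.5, 4, 7))) {
    mu <- case[1]; sigma <- case[2]; thr <- case[3]
    expect_equal(
      impute_p_within(mu, mu - 1.96 * sigma, mu + 1.96 * sigma, thr),
      quad(mu, sigma, thr),
      tolerance = 1e-6
    )
  }
  # increasing in threshold, decreasing in sigma at fixed mu
  p <- impute_p_within(2, -14, 18, seq(5, 30, by = 5))
  expect_true(all(diff(p) > 0))
  sig <- seq(4, 16, by = 2)
  p2 <- impute_p_within(2, 2 - 1.96 * sig, 2 + 1.96 * sig, 10)
  expect_true(all(diff(p2) < 0))
  expect_error(impute_p_within(0, 5, 5, 10), "degenerate")
  expect_error(impute_p_within(0, -5, 5, 0), "positive")
})

test_that("imputation reproduces published subgroup accuracy cells", {
  # Ralston rows of the weight-subgroup table: printed MPE and LOA only
  expect_equal(round(impute_p_within(0.2, -18.5, 18.9, 10), 1), 70.5)
  expect_equal(round(impute_p_within(0.2, -18.5, 18.9, 20), 1), 96.4)
  expect_equal(round(impute_p_within(-1.6, -23.2, 19.9, 10), 1), 63.2)
  expect_equal(round(impute_p_within(-1.6, -23.2, 19.9, 20), 1), 92.8)
})

test_that("McNemar switches variants correctly and matches stats oracles", {
  # continuity-corrected chi-square branch: (|30-10|-1)^2/40
  big <- mcnemar_paired(30, 10)
  expect_equal(big$statistic, 9.025)
  expect_equal(big$variant, "chi-square (continuity corrected)")
  m <- matrix(c(50, 30, 10, 50), 2)
  expect_equal(
    big$p_value, stats::mcnemar.test(m, correct = TRUE)$p.value
  )
  # exact branch: b = c gives p = 1
  expect_equal(mcnemar_paired(4, 4)$p_value, 1)
  expect_equal(mcnemar_paired(4, 4)$variant, "exact binomial")
  expect_error(mcnemar_paired(0, 0), "b \\+ c >= 1")
})

test_that("exact McNemar p equals tail enumeration and is symmetric", {
  enum <- function(b, c) {
    n <- b + c
    k <- min(b, c)
    # doubled lower tail of Bin(n, 1/2), term-by-term
    min(1, 2 * sum(vapply(0:k, function(i) stats::dbinom(i, n, 0.5), 1.0)))
  }
  for (b in 0:10) {
    for (c in 0:10) {
      if (b + c < 1 || b + c > 20) next
      expect_equal(mcnemar_paired(b, c)$p_value, enum(b, c),
        info = paste(b, c)
      )
      expect_equal(
        mcnemar_paired(b, c)$p_value, mcnemar_paired(c, b)$p_value
      )
      # independent check against the exact binomial test
      expect_equal(
        mcnemar_paired(b, c)$p_value,
        stats::binom.test(b, b + c, 0.5)$p.value,
        tolerance = 1e-12
      )
    }
  }
})

test_that("matched odds ratio and its CI are computed on the log scale", {
  expect_equal(paired_odds_ratio(7, 7)$odds_ratio, 1)
  or <- paired_odds_ratio(40, 10)
  expect_equal(or$odds_ratio, 4)
  expect_equal(or$ci_low, exp(log(4) - 1.96 * sqrt(1 / 40 + 1 / 10)))
  expect_equal(or$ci_high, exp(log(4) + 1.96 * sqrt(1 / 40 + 1 / 10)))
  expect_false(or$continuity_corrected)
  # zero cell: continuity-corrected alternative, flagged
  z <- paired_odds_ratio(5, 0)
  expect_true(z$continuity_corrected)
  expect_equal(z$odds_ratio, 5.5 / 0.5)
  # random tables against an independent log-scale recomputation
  set.seed(17)
  for (i in 1:20) {
    b <- sample(1:200, 1)
    c <- sample(1:200, 1)
    got <- paired_odds_ratio(b, c)
    se <- sqrt(1 / b + 1 / c)
    expect_equal(
      c(got$ci_low, got$ci_high),
      exp(log(b / c) + c(-1.96, 1.96) * se)
    )
  }
})

test_that("paired t-test matches the hand formula and handles degeneracy", {
  x <- c(1, 2, 3)
  expect_equal(paired_t(x, x)$p_value, 1)
  expect_true(paired_t(x, x)$degenerate)
  # constant nonzero difference is degenerate with p -> 0
  expect_equal(paired_t(x + 2, x)$p_value, 0)
  set.seed(19)
  a <- stats::rnorm(20, 1, 3)
  b <- stats::rnorm(20, 0, 3)
  d <- a - b
  tt <- paired_t(a, b)
  expect_equal(tt$t, mean(d) / (stats::sd(d) / sqrt(20)))
  expect_equal(
    tt$p_value, 2 * stats::pt(abs(tt$t), df = 19, lower.tail = FALSE)
  )
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("accuracy differences reproduce the headline contrasts", {
  expect_equal(unlist(difference_summary(50, 50)[, c(1, 2)]),
    c(absolute = 0, relative = 0)
  )
  expect_equal(difference_summary(79.3, 55.5)$relative_int, 43)
  expect_equal(difference_summary(79.3, 67.4)$relative_int, 18)
  expect_equal(difference_summary(79.3, 55.5)$absolute_int, 24)
  expect_true(is.na(difference_summary(10, 0)$relative))
})
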