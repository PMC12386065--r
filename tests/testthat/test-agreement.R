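test_that("pearson_with_p matches the t-transform and handles degeneracy", {
  # exact line
  expect_equal(pearson_with_p(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 3, 4))$r, 1)
  # hand-computed: r = 0.5, p = 2/3 on 1 df
  pr <- pearson_with_p(c(1, 2, 3), c(1, 3, 2))
  expect_equal(pr$r, 0.5, tolerance = 1e-12)
  expect_equal(pr$p, 2 / 3, tolerance = 1e-6)
  # cross-check against the explicit-arithmetic oracle on random pairs
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(12); y <- 0.6 * x + rnorm(12)
    pr <- pearson_with_p(x, y)
    po <- pearson_oracle(x, y)
    expect_equal(pr$r, po$r, tolerance = 1e-10)
    expect_equal(pr$p, po$p, tolerance = 1e-10)
  }
  expect_error(pearson_with_p(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("pearson r is affine-invariant with sign tracking the slope", {
  set.seed(22)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, sd = 0.5)
  r0 <- pearson_with_p(x, y)$r
  expect_equal(pearson_with_p(3 * x + 7, y)$r, r0)
  expect_equal(pearson_with_p(x, 0.1 * y - 2)$r, r0)
  expect_equal(pearson_with_p(-2 * x + 1, y)$r, -r0)
})

test_that("paired t-test handles trivial and degenerate difference patterns", {
  x <- c(5, 7, 9, 11)
  tt <- paired_t(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  # diffs {1, -1, 0, 0}: mean 0, t = 0
  tt <- paired_t(c(2, 1, 3, 4), c(1, 2, 3, 4))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  # constant nonzero difference with zero spread: underflow-capped p
  tt <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_identical(tt$t, Inf)
  expect_lte(tt$p, 1e-300)
  expect_error(paired_t(1, 1), "at least 2")
})

test_that("bland_altman computes bias, SD of differences and LoA", {
  # constant difference: zero-width limits
  ba <- bland_altman(c(3, 4, 5), c(1, 2, 3))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_low, 2)
  expect_equal(ba$loa_high, 2)
  # sample (n-1) SD and the fixed 1.96 multiplier, checked by hand
  m <- c(10, 12, 14, 16); a <- c(9, 13, 12, 17)
  d <- m - a
  ba <- bland_altman(m, a)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 3))
  expect_equal(ba$loa_high, mean(d) + 1.96 * ba$sd_diff)
  expect_equal(ba$coords$average, (m + a) / 2)
  expect_equal(ba$coords$difference, d)
})

test_that("closed-form LoA reproduce the published summary values", {
  loa <- loa_from_summary(-0.80, 1.64)
  expect_equal(loa$loa_high, 2.41, tolerance = 0.01 / 2.41)
  expect_equal(loa$loa_low, -4.01, tolerance = 0.01 / 4.01)
  loa <- loa_from_summary(-0.35, 1.33)
  expect_equal(loa$loa_high, 2.26, tolerance = 0.01 / 2.26)
  expect_equal(loa$loa_low, -2.96, tolerance = 0.01 / 2.96)
})

test_that("LoA cover ~95% of normal differences at large n", {
  set.seed(23)
  d <- rnorm(1e5, mean = 0.3, sd = 1.2)
  ba <- bland_altman(d, rep(0, length(d)))
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_equal(cover, 0.95, tolerance = 0.01 / 0.95)
})

test_that("ICC(2,1) matches hand ANOVA cases and flags bad input", {
  expect_equal(icc_2_1(cbind(c(1, 2, 3), c(1, 2, 3))), 1)
  # hand ANOVA: MSR = 2, MSC = 1.5, MSE = 0 -> 2 / 3
  expect_equal(icc_2_1(cbind(c(1, 2, 3), c(2, 3, 4))), 2 / 3,
               tolerance = 1e-12)
  # no between-subject variance: non-positive ICC (up to float rounding)
  expect_lt(icc_2_1(cbind(rep(5, 4), rep(7, 4))), 1e-12)
  expect_error(icc_2_1(cbind(c(1, NA, 3), c(2, 3, 4))), "incomplete")
  expect_error(icc_2_1(cbind(1, 2)), "at least 2 subjects")
})

test_that("ICC(2,1) agrees with the brute-force ANOVA oracle", {
  set.seed(24)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, mean = 10, sd = 3), n, k) +
      rnorm(n, sd = 2)  # subject effects recycled down columns
    expect_equal(icc_2_1(x), icc_oracle(x), tolerance = 1e-9)
  }
})

test_that("CV of differences uses the grand-mean convention", {
  expect_equal(cv_from_summary(0.71, 6.5, 6.4), 11.0, tolerance = 0.1 / 11.0)
  expect_equal(cv_from_summary(1.64, 29.5, 30.3), 5.5, tolerance = 0.1 / 5.5)
  expect_equal(cv_from_summary(1.33, 17.9, 18.5), 7.32,
               tolerance = 0.1 / 7.32)
  expect_equal(cv_differences(c(5, 6, 7), c(5, 6, 7)), 0)
  expect_error(cv_from_summary(1, 2, -2), "grand mean")
  # data route consistent with the summary route
  m <- c(10, 12, 14); a <- c(11, 11, 15)
  expect_equal(cv_differences(m, a),
               cv_from_summary(sd(m - a), mean(m), mean(a)))
})

test_that("SEM conventions and the MDC95 chain reproduce published values", {
  expect_equal(sem_measurement(0.71, icc = 0.95, mode = "group"), 0.16,
               tolerance = 0.005 / 0.16)
  expect_equal(sem_measurement(1.64, icc = 0.92, mode = "group"), 0.46,
               tolerance = 0.005 / 0.46)
  expect_equal(sem_measurement(1.33, mode = "pooled"), 0.94,
               tolerance = 0.005 / 0.94)
  expect_equal(sem_measurement(2, icc = 1, mode = "group"), 0)
  expect_error(sem_measurement(1, icc = 1.2, mode = "group"), "\\[0, 1\\]")
  expect_error(sem_measurement(1, mode = "group"), "requires")

  expect_equal(mdc95(0.94), 2.61, tolerance = 0.005 / 2.61)
  expect_equal(mdc95(0), 0)
  expect_equal(mdc95(1.0), 2.772, tolerance = 0.001)
  # algebraic identity: mdc95(sem(sd, icc, A)) = 1.96 sqrt(2) sqrt(1-icc) sd
  for (sd_d in c(0.5, 1.64)) {
    for (icc in c(0, 0.5, 0.92)) {
      expect_equal(mdc95(sem_measurement(sd_d, icc = icc, mode = "group")),
                   1.96 * sqrt(2) * sqrt(1 - icc) * sd_d)
    }
  }
})

test_that("repeatability recovers the within-subject SD", {
  # identical duplicates
  x <- cbind(c(4, 5, 6), c(4, 5, 6))
  rr <- repeatability(x)
  expect_equal(rr$rc, 0)
  # duplicates differing by a constant d: sw = d / sqrt(2), RC = 1.96 d
  d <- 0.8
  x <- cbind(c(4, 5, 6, 7), c(4, 5, 6, 7) + d)
  rr <- repeatability(x)
  expect_equal(rr$sw, d / sqrt(2))
  expect_equal(rr$rc, 1.96 * d)
  expect_true(rr$ci_low < rr$rc && rr$rc < rr$ci_high)
  # consistency: sw estimated within 2% at n = 1e4
  spec <- duplicate_spec(1e4, grand_mean = 20, sd_between = 4, sw = 3.8,
                         seed = 77)
  rr <- repeatability(generate_duplicates(spec))
  expect_equal(rr$sw, 3.8, tolerance = 0.02)
  expect_equal(rr$rc, 1.96 * sqrt(2) * 3.8, tolerance = 0.02)
  expect_error(repeatability(cbind(c(1, NA), c(2, 3))), "complete")
  expect_error(repeatability(matrix(1:3, ncol = 1)), "2 repeats")
})

test_that("RC chi-square interval reproduces published CIs and converges", {
  ci <- rc_confidence_interval(5.66, 15)
  expect_equal(ci$ci_low, 4.15, tolerance = 0.01 / 4.15)
  expect_equal(ci$ci_high, 8.93, tolerance = 0.01 / 8.93)
  ci <- rc_confidence_interval(0.82, 15)
  expect_equal(ci$ci_low, 0.60, tolerance = 0.01 / 0.60)
  expect_equal(ci$ci_high, 1.29, tolerance = 0.01 / 1.29)
  ci <- rc_confidence_interval(10.53, 15)
  expect_equal(ci$ci_low, 7.71, tolerance = 0.01 / 7.71)
  expect_equal(ci$ci_high, 16.61, tolerance = 0.01 / 16.61)
  # both df conventions available; the interval degenerates as n grows
  ci <- rc_confidence_interval(3, 1e6)
  expect_equal(ci$ci_low, 3, tolerance = 1e-2)
  expect_equal(ci$ci_high, 3, tolerance = 1e-2)
  wide <- rc_confidence_interval(3, 15, df_convention = "n-1")
  narrow <- rc_confidence_interval(3, 15, df_convention = "n(m-1)")
  expect_lt(narrow$ci_high, wide$ci_high)
  expect_error(rc_confidence_interval(3, 1), "at least 2")
})

test_that("RC interval brackets the true value at the nominal rate", {
  set.seed(25)
  sw_true <- 2.5
  rc_true <- 1.96 * sqrt(2) * sw_true
  n <- 15
  hits <- vapply(seq_len(2000), function(i) {
    x <- matrix(rnorm(n * 2, sd = sw_true), n, 2) + rnorm(n, sd = 5)
    rr <- repeatability(x)
    rr$ci_low <= rc_true && rc_true <= rr$ci_high
  }, logical(1))
  expect_equal(mean(hits), 0.95, tolerance = 0.02 / 0.95)
})

test_that("Fisher-z correlation power matches its null case and Monte Carlo", {
  expect_gt(power_correlation(0.80, 30), 0.99)
  expect_equal(power_correlation(0, 50), 0.05, tolerance = 1e-10)
  expect_equal(power_correlation(0.5, 10000), 1.0, tolerance = 1e-9)
  expect_error(power_correlation(1, 30), "rho")
  expect_error(power_correlation(0.5, 3), "n >= 4")
  # Monte-Carlo rejection rate of the r-test at n = 30
  set.seed(26)
  for (rho in c(0.5, 0.8)) {
    rej <- vapply(seq_len(2e4), function(i) {
      xy <- rbiv(30, rho)
      r <- cor(xy[, 1], xy[, 2])
      t <- r * sqrt(28 / (1 - r^2))
      2 * pt(-abs(t), 28) < 0.05
    }, logical(1))
    expect_lt(abs(mean(rej) - power_correlation(rho, 30)), 0.01)
  }
})

test_that("KS normality check distinguishes normal from uniform samples", {
  set.seed(27)
  x <- rnorm(200, mean = 10, sd = 2)
  expect_gt(ks_normality(x)$p, 0.05)
  u <- runif(1000)
  expect_lt(ks_normality(u, lilliefors = TRUE)$p, 0.05)
  # the classical variant is conservative relative to Lilliefors
  expect_gte(ks_normality(u)$statistic,
             ks_normality(u, lilliefors = TRUE)$statistic - 1e-12)
  expect_identical(ks_normality(x)$method, "ks_estimated_params")
  expect_identical(ks_normality(x, lilliefors = TRUE)$method, "lilliefors")
  expect_error(ks_normality(rep(3, 10)), "zero variance")
  expect_error(ks_normality(1:4), "at least 5")
})

test_that("categorical comparison picks chi-square or Fisher as appropriate", {
  res <- compare_counts(matrix(c(22, 5, 8, 25), 2))
  expect_lt(res$p, 1e-4)
  res <- compare_counts(matrix(c(10, 10, 10, 10), 2))
  expect_identical(res$method, "chi-square")
  expect_equal(res$p, 1)
  res <- compare_counts(matrix(c(1, 0, 0, 1), 2))
  expect_identical(res$method, "fisher")
  expect_equal(res$p, 1)
  expect_error(compare_counts(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(compare_counts(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("agreement_report bundles every statistic consistently", {
  set.seed(28)
  m <- rnorm(30, 20, 4)
  a <- m + rnorm(30, -0.3, 1.2)
  rep <- agreement_report(m, a, sem_mode = "group")
  expect_equal(rep$bias, mean(m - a))
  expect_equal(rep$loa_high, rep$bias + 1.96 * rep$sd_diff)
  expect_equal(rep$loa_low, rep$bias - 1.96 * rep$sd_diff)
  expect_equal(rep$r, cor(m, a))
  expect_equal(rep$icc, icc_oracle(cbind(m, a)), tolerance = 1e-9)
  expect_equal(rep$mdc95, 1.96 * sqrt(2) * rep$sem)
  expect_identical(rep$sem_mode, "group")
  expect_true(-1 <= rep$icc && rep$icc <= 1)
  # pooled convention: SEM decoupled from the ICC
  rep_b <- agreement_report(m, a, sem_mode = "pooled")
  expect_equal(rep_b$sem, rep$sd_diff / sqrt(2))
})

test_that("subgroup agreement is consistent with the whole-cohort report", {
  set.seed(29)
  n <- 40
  df <- data.frame(
    manual_lasr_pct = rnorm(n, 20, 5),
    lavi_ml_m2 = c(rnorm(n / 2, 50, 8), rnorm(n / 2, 25, 5)),
    ef_pct = rep(60, n),
    age_years = runif(n, 30, 90),
    sex = rep(c("m", "f"), n / 2))
  df$auto_lasr_pct <- df$manual_lasr_pct + rnorm(n, 0, 1)
  # one stratum equal to the whole cohort reproduces the overall numbers
  whole <- subgroup_agreement(df, list(all = function(d) rep(TRUE, n)))
  overall <- agreement_report(df$manual_lasr_pct, df$auto_lasr_pct)
  expect_equal(whole$r, overall$r)
  expect_equal(whole$icc, overall$icc)
  expect_equal(whole$n, n)
  # complementary strata partition the cohort
  tab <- subgroup_agreement(df, "lavi")
  expect_equal(sum(tab$n), n)
  tab <- subgroup_agreement(df, "sex")
  expect_equal(sum(tab$n), n)
  # empty / tiny strata are skipped with a warning, not an error
  expect_warning(tab <- subgroup_agreement(df, "ef"), "skipped")
  expect_true(tab$skipped[tab$stratum == "EF reduced (< 50%)"])
  # a stratum built with lower noise shows the higher ICC
  df2 <- df
  noisy <- df2$lavi_ml_m2 <= 34
  df2$auto_lasr_pct[noisy] <- df2$manual_lasr_pct[noisy] +
    rnorm(sum(noisy), 0, 4)
  tab2 <- subgroup_agreement(df2, "lavi")
  expect_gt(tab2$icc[1], tab2$icc[2])
})
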