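#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation between the manual and automatic measurements,
#' with the usual two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (as computed by [stats::cor.test()]).
#'
#' @param manual,automatic Numeric vectors of equal length (strain, %).
#' @return List with `r`, `p` and `n`.
#' @examples
#' pearson_with_p(c(1, 2, 3), c(1, 1.9, 3.2))
#' @export
pearson_with_p <- function(manual, automatic) {
  .check_pairs(manual, automatic, min_n = 3L)
  if (stats::sd(manual) == 0 || stats::sd(automatic) == 0) {
    stop("degenerate input: zero variance in one of the measurement columns",
         call. = FALSE)
  }
  ct <- stats::cor.test(manual, automatic, method = "pearson")
  list(r = unname(ct$estimate), p = .floor_p(ct$p.value),
       n = length(manual))
}

#' Paired t-test on manual - automatic differences
#'
#' @param manual,automatic Numeric vectors of equal length.
#' @return List with `t`, `p`, `df` and mean difference `estimate`.
#' @export
paired_t <- function(manual, automatic) {
  .check_pairs(manual, automatic, min_n = 2L)
  d <- manual - automatic
  if (stats::sd(d) == 0) {
    # zero spread: t is 0 (d == 0 everywhere) or infinite; cap p as underflow
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = length(d) - 1L, estimate = 0))
    }
    return(list(t = sign(mean(d)) * Inf, p = .P_FLOOR,
                df = length(d) - 1L, estimate = mean(d)))
  }
  tt <- stats::t.test(manual, automatic, paired = TRUE)
  list(t = unname(tt$statistic), p = .floor_p(tt$p.value),
       df = unname(tt$parameter), estimate = unname(tt$estimate))
}

#' Bland-Altman analysis of paired measurements
#'
#' Bias is the mean of the paired differences `manual - automatic`; the limits
#' of agreement are `bias +/- z * SD` of the differences (sample SD, `n - 1`
#' denominator; `z = 1.96` by convention). Per-patient Bland-Altman plot
#' coordinates (average on x, difference on y) are returned alongside.
#'
#' @param manual,automatic Numeric vectors of equal length.
#' @param z Limit-of-agreement multiplier, default 1.96.
#' @return Object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, `z` and a data frame `coords` with columns
#'   `average` and `difference`.
#' @export
bland_altman <- function(manual, automatic, z = 1.96) {
  .check_pairs(manual, automatic, min_n = 2L)
  d <- manual - automatic
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - z * sd_diff, loa_high = bias + z * sd_diff,
         n = length(d), z = z,
         coords = data.frame(average = (manual + automatic) / 2,
                             difference = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f, SD %.2f, LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Limits of agreement from printed summary statistics
#'
#' Closed form `bias +/- z * sd_diff` for use when only the summary pair
#' (bias, SD of differences) is available, e.g. from a published table.
#'
#' @param bias Mean difference.
#' @param sd_diff SD of the differences.
#' @param z Multiplier, default 1.96.
#' @return List with `loa_low` and `loa_high`.
#' @examples
#' loa_from_summary(-0.80, 1.64)  # c(-4.01, 2.41)
#' @export
loa_from_summary <- function(bias, sd_diff, z = 1.96) {
  if (sd_diff < 0) stop("`sd_diff` must be non-negative", call. = FALSE)
  list(loa_low = bias - z * sd_diff, loa_high = bias + z * sd_diff)
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-measurement intraclass correlation under the two-way random-effects
#' model with absolute agreement. From the two-way ANOVA mean squares --
#' between-subject `MSR`, between-rater `MSC`, residual `MSE` -- for `n`
#' subjects and `k` raters:
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#'
#' @param x Numeric matrix, subjects in rows, raters/methods in columns.
#'   Must be complete (no `NA`); no imputation is performed.
#' @return The ICC estimate (can be negative when between-subject variance is
#'   small relative to error).
#' @examples
#' icc_2_1(cbind(c(1, 2, 3), c(2, 3, 4)))  # 2/3
#' @export
icc_2_1 <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    stop("incomplete rating matrix: missing values are not imputed",
         call. = FALSE)
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  }
  long <- data.frame(value = as.vector(x),
                     subject = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  # F-tests are not used, only the mean squares; suppress aov's complaint
  # about perfect fits (MSE = 0 is a legitimate input here)
  ms <- suppressWarnings(
    stats::anova(stats::aov(value ~ subject + rater, data = long)))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Coefficient of variation of the between-method differences
#'
#' `100 * sd_diff / grand mean`, where the grand mean is the mean of the two
#' per-method means. Expressing the difference SD relative to the overall
#' measurement level makes agreement comparable across cohorts whose strain
#' magnitudes differ several-fold.
#'
#' @param manual,automatic Numeric vectors of equal length.
#' @return CV in percent.
#' @export
cv_differences <- function(manual, automatic) {
  .check_pairs(manual, automatic, min_n = 2L)
  cv_from_summary(stats::sd(manual - automatic),
                  mean(manual), mean(automatic))
}

#' @rdname cv_differences
#' @param sd_diff SD of the paired differences.
#' @param mean_manual,mean_automatic The two method means.
#' @export
cv_from_summary <- function(sd_diff, mean_manual, mean_automatic) {
  grand <- (mean_manual + mean_automatic) / 2
  if (grand == 0) {
    stop("grand mean is zero: CV undefined", call. = FALSE)
  }
  100 * sd_diff / grand
}

#' Standard error of measurement
#'
#' Two conventions are exposed behind `mode`:
#' \describe{
#'   \item{`"group"` (mode A)}{`sd_diff * sqrt(1 - icc)` -- the reliability-
#'     based SEM computed per cohort from the difference SD and the cohort
#'     ICC.}
#'   \item{`"pooled"` (mode B)}{`sd_diff / sqrt(2)` -- the within-subject SD
#'     implied by the difference SD when the two methods are treated as
#'     exchangeable repeats.}
#' }
#' Both are legitimate and appear side by side in the method-comparison
#' literature; reports label which convention produced each value.
#'
#' @param sd_diff SD of the paired differences (%).
#' @param icc Reliability estimate in `[0, 1]`; required for mode `"group"`.
#' @param mode `"group"` or `"pooled"`.
#' @return SEM in the units of the measurements.
#' @export
sem_measurement <- function(sd_diff, icc = NULL,
                            mode = c("group", "pooled")) {
  mode <- match.arg(mode)
  if (sd_diff < 0) stop("`sd_diff` must be non-negative", call. = FALSE)
  if (mode == "group") {
    if (is.null(icc)) stop("mode \"group\" requires `icc`", call. = FALSE)
    if (icc < 0 || icc > 1) {
      stop("`icc` must lie in [0, 1] for mode \"group\"", call. = FALSE)
    }
    sd_diff * sqrt(1 - icc)
  } else {
    sd_diff / sqrt(2)
  }
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = 1.96 * sqrt(2) * SEM`: the smallest change between two
#' measurements exceeding measurement noise with 95% confidence.
#'
#' @param sem Standard error of measurement (>= 0).
#' @return MDC95 in the units of the measurements.
#' @examples
#' mdc95(0.94)  # 2.61
#' @export
mdc95 <- function(sem) {
  if (any(sem < 0)) stop("`sem` must be non-negative", call. = FALSE)
  1.96 * sqrt(2) * sem
}

#' Repeatability from duplicate measurements
#'
#' Within-subject SD and Bland-Altman repeatability coefficient from an
#' `n x m` matrix of repeated measurements (one subject per row). The
#' within-subject SD is `sw = sqrt(SSE / (n (m - 1)))` with
#' `SSE = sum_i sum_j (x_ij - xbar_i)^2`; for duplicates (`m = 2`) this
#' reduces to `sqrt(sum(d_i^2) / (2 n))` over the within-subject differences.
#' The repeatability coefficient is `RC = 1.96 * sqrt(2) * sw`, the bound
#' below which 95% of test-retest differences are expected to fall. Its
#' confidence interval comes from [rc_confidence_interval()].
#'
#' @param x Numeric matrix of repeated measurements, subjects in rows.
#' @param level Confidence level for the RC interval, default 0.95.
#' @param df_convention Degrees of freedom for the chi-square interval, see
#'   [rc_confidence_interval()].
#' @return Object of class `repeatability_result`: list with `sw`, `rc`,
#'   `ci_low`, `ci_high`, `n`, `replicates`.
#' @export
repeatability <- function(x, level = 0.95,
                          df_convention = c("n-1", "n(m-1)")) {
  df_convention <- match.arg(df_convention)
  x <- as.matrix(x)
  if (anyNA(x)) {
    stop("every subject needs a complete set of repeats", call. = FALSE)
  }
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (m < 2L) stop("need at least 2 repeats per subject", call. = FALSE)
  sse <- sum((x - rowMeans(x))^2)
  sw <- sqrt(sse / (n * (m - 1)))
  rc <- 1.96 * sqrt(2) * sw
  ci <- rc_confidence_interval(rc, n, level = level, m = m,
                               df_convention = df_convention)
  structure(
    list(sw = sw, rc = rc, ci_low = ci$ci_low, ci_high = ci$ci_high,
         n = n, replicates = m, level = level,
         df_convention = df_convention),
    class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "Repeatability (n = %d, %d repeats): sw %.2f, RC %.2f (%.0f%% CI %.2f-%.2f)\n",
    x$n, x$replicates, x$sw, x$rc, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Chi-square confidence interval for a repeatability coefficient
#'
#' Scales the point estimate by `sqrt(df / qchisq(p, df))`, the usual
#' chi-square interval for a standard deviation applied to the RC. Two
#' degrees-of-freedom conventions are available: `df = n - 1` (default) and
#' the textbook `df = n (m - 1)` for `m` repeats per subject.
#'
#' @param rc Repeatability coefficient point estimate.
#' @param n Number of subjects.
#' @param level Confidence level, default 0.95.
#' @param m Repeats per subject (used only by the `"n(m-1)"` convention).
#' @param df_convention `"n-1"` or `"n(m-1)"`.
#' @return List with `ci_low` and `ci_high`.
#' @examples
#' rc_confidence_interval(5.66, 15)  # 4.15 - 8.93
#' @export
rc_confidence_interval <- function(rc, n, level = 0.95, m = 2,
                                   df_convention = c("n-1", "n(m-1)")) {
  df_convention <- match.arg(df_convention)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (rc < 0) stop("`rc` must be non-negative", call. = FALSE)
  df <- if (df_convention == "n-1") n - 1 else n * (m - 1)
  alpha <- 1 - level
  list(ci_low = rc * sqrt(df / stats::qchisq(1 - alpha / 2, df)),
       ci_high = rc * sqrt(df / stats::qchisq(alpha / 2, df)))
}

#' Post hoc power for detecting a correlation
#'
#' Fisher-z approximation: the transformed sample correlation `atanh(r)` is
#' approximately normal with mean `atanh(rho) + rho / (2 (n - 1))` (the
#' standard small-sample bias term) and SD `1 / sqrt(n - 3)`, so with
#' `z_rho` that mean,
#' \deqn{power = \Phi(|z_\rho|\sqrt{n-3} - z_{1-\alpha/2}) +
#'               \Phi(-|z_\rho|\sqrt{n-3} - z_{1-\alpha/2})}
#' (the second term is negligible except near the null, where the bias term
#' also vanishes so the null case returns exactly `alpha`).
#'
#' @param rho Population correlation, `|rho| < 1`.
#' @param n Sample size, >= 4.
#' @param alpha Two-sided significance level, default 0.05.
#' @return Power in `[0, 1]`.
#' @examples
#' power_correlation(0.80, 30)  # > 0.99
#' @export
power_correlation <- function(rho, n, alpha = 0.05) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  za <- abs(atanh(rho) + rho / (2 * (n - 1))) * sqrt(n - 3)
  zcrit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(za - zcrit) + stats::pnorm(-za - zcrit)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal distribution with mean and SD estimated
#' from the sample. With `lilliefors = FALSE` (default) the p-value comes from
#' the classical asymptotic KS distribution, which is conservative when the
#' parameters are estimated; `lilliefors = TRUE` applies the Lilliefors
#' correction (via [nortest::lillie.test()]), which accounts for the
#' estimation.
#'
#' @param values Numeric vector, n >= 5, non-degenerate.
#' @param lilliefors Use the Lilliefors-corrected p-value.
#' @return List with `statistic`, `p` and `method`.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) {
    stop("need at least 5 finite values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  if (lilliefors) {
    kt <- nortest::lillie.test(values)
    list(statistic = unname(kt$statistic), p = kt$p.value,
         method = "lilliefors")
  } else {
    kt <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
    list(statistic = unname(kt$statistic), p = kt$p.value,
         method = "ks_estimated_params")
  }
}

#' Compare categorical counts between two groups
#'
#' Pearson chi-square test when every expected cell count is at least 5,
#' otherwise Fisher's exact test (two-sided). Returns which test was used.
#'
#' @param tab 2x2 (or r x c) matrix of non-negative integer counts.
#' @return List with `p` and `method` (`"chi-square"` or `"fisher"`).
#' @export
compare_counts <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = FALSE)
    list(p = .floor_p(ct$p.value), method = "chi-square")
  } else {
    ft <- stats::fisher.test(tab)
    list(p = .floor_p(ft$p.value), method = "fisher")
  }
}

#' Full agreement report for one cohort
#'
#' Bundles every agreement statistic for a set of paired measurements:
#' Pearson r with p, paired-t bias test, Bland-Altman bias / SD of
#' differences / limits of agreement, ICC(2,1) on the n x 2 method matrix,
#' CV of the differences, SEM (labelled with its convention) and MDC95.
#'
#' @param manual,automatic Numeric vectors of equal length (>= 3).
#' @param sem_mode SEM convention, `"group"` or `"pooled"`; see
#'   [sem_measurement()].
#' @param z Limit-of-agreement multiplier.
#' @return Object of class `agreement_report` (a named list; see fields in
#'   the details).
#' @export
agreement_report <- function(manual, automatic,
                             sem_mode = c("group", "pooled"), z = 1.96) {
  sem_mode <- match.arg(sem_mode)
  .check_pairs(manual, automatic, min_n = 3L)
  ba <- bland_altman(manual, automatic, z = z)
  pr <- pearson_with_p(manual, automatic)
  tt <- paired_t(manual, automatic)
  icc <- icc_2_1(cbind(manual, automatic))
  sem <- if (sem_mode == "group") {
    # reliability-based SEM needs a non-negative ICC; fall back to pooled
    # with a warning when between-subject variance is degenerate
    if (icc < 0) {
      warning("negative ICC: group-convention SEM undefined, using pooled",
              call. = FALSE)
      sem_measurement(ba$sd_diff, mode = "pooled")
    } else {
      sem_measurement(ba$sd_diff, icc = icc, mode = "group")
    }
  } else {
    sem_measurement(ba$sd_diff, mode = "pooled")
  }
  structure(
    list(n = ba$n, r = pr$r, p_r = pr$p,
         t = tt$t, p_t = tt$p,
         bias = ba$bias, sd_diff = ba$sd_diff,
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         icc = icc,
         cv_pct = cv_differences(manual, automatic),
         sem = sem, mdc95 = mdc95(sem), sem_mode = sem_mode,
         mean_manual = mean(manual), sd_manual = stats::sd(manual),
         mean_automatic = mean(automatic), sd_automatic = stats::sd(automatic),
         grand_mean = (mean(manual) + mean(automatic)) / 2,
         coords = ba$coords),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d)\n", x$n))
  cat(sprintf("  manual %.1f +/- %.1f, automatic %.1f +/- %.1f\n",
              x$mean_manual, x$sd_manual, x$mean_automatic, x$sd_automatic))
  cat(sprintf("  r = %.3f (p %s), ICC(2,1) = %.3f\n",
              x$r, .format_p(x$p_r), x$icc))
  cat(sprintf("  bias %.2f +/- %.2f, LoA [%.2f, %.2f]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  CV %.1f%%, SEM %.2f (%s), MDC95 %.2f\n",
              x$cv_pct, x$sem, x$sem_mode, x$mdc95))
  invisible(x)
}

#' Subgroup agreement analysis
#'
#' Agreement statistics per stratum of a paired-sample table: count, mean
#' absolute difference, Pearson r and ICC(2,1). The built-in stratifiers
#' mirror standard clinical cut-points: LA enlargement (LAVi > 34 mL/m^2),
#' preserved vs reduced ejection fraction (EF >= 50%), age >= 65, and sex.
#'
#' @param df Data frame with columns `manual_lasr_pct`, `auto_lasr_pct` and
#'   whatever covariates the stratifier needs (`lavi_ml_m2`, `ef_pct`,
#'   `age_years`, `sex`).
#' @param stratifier One of `"lavi"`, `"ef"`, `"age"`, `"sex"`, or a named
#'   list of predicates (functions of `df` returning a logical vector).
#' @param min_n Strata smaller than this are reported as skipped with a
#'   warning (correlation needs at least 3 pairs).
#' @return Data frame with one row per stratum: `stratum`, `n`,
#'   `mean_abs_diff`, `r`, `icc`, `skipped`.
#' @export
subgroup_agreement <- function(df, stratifier = "lavi", min_n = 3L) {
  preds <- if (is.character(stratifier)) {
    .builtin_stratifier(match.arg(stratifier, c("lavi", "ef", "age", "sex")))
  } else {
    stratifier
  }
  rows <- lapply(names(preds), function(nm) {
    keep <- preds[[nm]](df)
    keep[is.na(keep)] <- FALSE
    n <- sum(keep)
    if (n < min_n) {
      warning(sprintf("stratum \"%s\" has n = %d < %d: skipped", nm, n, min_n),
              call. = FALSE)
      return(data.frame(stratum = nm, n = n, mean_abs_diff = NA_real_,
                        r = NA_real_, icc = NA_real_, skipped = TRUE))
    }
    m <- df$manual_lasr_pct[keep]
    a <- df$auto_lasr_pct[keep]
    data.frame(stratum = nm, n = n,
               mean_abs_diff = mean(abs(m - a)),
               r = pearson_with_p(m, a)$r,
               icc = icc_2_1(cbind(m, a)),
               skipped = FALSE)
  })
  do.call(rbind, rows)
}

.builtin_stratifier <- function(which) {
  switch(which,
    lavi = list(
      "LA enlarged (LAVi > 34)" = function(d) d$lavi_ml_m2 > 34,
      "LA normal (LAVi <= 34)" = function(d) d$lavi_ml_m2 <= 34),
    ef = list(
      "EF preserved (>= 50%)" = function(d) d$ef_pct >= 50,
      "EF reduced (< 50%)" = function(d) d$ef_pct < 50),
    age = list(
      "Age >= 65" = function(d) d$age_years >= 65,
      "Age < 65" = function(d) d$age_years < 65),
    sex = list(
      "Male" = function(d) d$sex == "m",
      "Female" = function(d) d$sex == "f"))
}

# p-values below this are reported at the bound (underflow-capped), matching
# the "< 10^-k" presentation style of clinical tables
.P_FLOOR <- 1e-300

.floor_p <- function(p) max(p, .P_FLOOR)

.format_p <- function(p) {
  if (p <= .P_FLOOR) "< 1e-300"
  else if (p < 1e-4) sprintf("< 1e%d", ceiling(log10(p)))
  else sprintf("= %.4f", p)
}

.check_pairs <- function(manual, automatic, min_n = 2L) {
  if (length(manual) != length(automatic)) {
    stop("`manual` and `automatic` must have equal length", call. = FALSE)
  }
  if (length(manual) < min_n) {
    stop(sprintf("need at least %d pairs (got %d)", min_n, length(manual)),
         call. = FALSE)
  }
  if (any(!is.finite(manual)) || any(!is.finite(automatic))) {
    stop("measurements must be finite", call. = FALSE)
  }
  invisible(TRUE)
}
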