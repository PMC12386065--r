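# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit arithmetic only.

# ICC(2,1) by brute-force two-way ANOVA sums of squares
icc_oracle <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Pearson r and its two-sided p by hand (t transform, n - 2 df)
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# seeded correlated pair generator for Monte-Carlo checks (plain rnorm +
# mixing, independent of MASS::mvrnorm)
rbiv <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}
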