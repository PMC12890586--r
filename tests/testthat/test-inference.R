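test_that("one-sample t-test: symmetric data, printed-scale calibration, df", {
  sym <- c(-2, 2, -1, 1, -0.5, 0.5)
  tt <- regional_ttest(sym)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_true(tt$ci[1] <= tt$mean && tt$mean <= tt$ci[2])
  expect_equal(regional_ttest(rnorm(180))$df, 179)
  expect_error(regional_ttest(rep(1, 10)), "zero variance")
  expect_error(regional_ttest(1), "at least 2")
})

test_that("t-test p-value matches a normal-approximation oracle for n >= 30", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(60, mean = runif(1, -0.3, 0.3))
    tt <- regional_ttest(x)
    p_norm <- 2 * stats::pnorm(-abs(tt$t))
    expect_lt(abs(tt$p - p_norm), 0.01)
  }
})

test_that("balanced bootstrap is deterministic under a seed and df is k*n-1", {
  set.seed(31)
  values <- rnorm(300)
  region <- rep(c("NA", "CA", "WA", "GU", "CEA", "SA"), each = 50)
  a <- balanced_bootstrap_ttest(values, region, n_per_region = 30,
                                reps = 50, seed = 4)
  b <- balanced_bootstrap_ttest(values, region, n_per_region = 30,
                                reps = 50, seed = 4)
  expect_identical(a, b)
  expect_equal(a$df, 179)
  expect_error(balanced_bootstrap_ttest(values[1:60], region[1:60],
                                        n_per_region = 30, reps = 2),
               "fewer than")
})

test_that("balanced bootstrap recovers a true shifted mean within MC error", {
  set.seed(32)
  region <- rep(c("NA", "CA", "WA", "GU", "CEA", "SA"), each = 60)
  values <- rnorm(length(region), mean = 0.5)
  bt <- balanced_bootstrap_ttest(values, region, reps = 400, seed = 1)
  # MC oracle: subsample means are unbiased for the pooled mean here;
  # 3 * SE of the overall sample mean bounds the deviation generously
  expect_lt(abs(bt$mean_of_means - 0.5), 3 / sqrt(length(region)) * 3)
})

test_that("balanced bootstrap targets the unweighted mean of regional means", {
  set.seed(33)
  # unbalanced: one region has many plots and a different mean
  region <- c(rep("A", 300), rep("B", 40), rep("C", 40))
  values <- c(rnorm(300, 3), rnorm(40, 0), rnorm(40, 0))
  bt <- balanced_bootstrap_ttest(values, region, n_per_region = 30,
                                 reps = 600, seed = 2)
  unweighted <- mean(tapply(values, region, mean))   # ~1
  pooled <- mean(values)                             # ~2.4
  expect_lt(abs(bt$mean_of_means - unweighted), 0.15)
  expect_gt(abs(bt$mean_of_means - pooled), 1)
})

test_that("bivariate regression recovers exact lines and flags curvature", {
  x <- 1:20
  fit <- suppressWarnings(bivariate_regression(2 * x + 1, x))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_false(fit$polynomial_preferred)
  x2 <- -3:3
  fit2 <- bivariate_regression(x2^2, x2)
  expect_true(fit2$polynomial_preferred)
  expect_error(bivariate_regression(rnorm(10), rep(1, 10)), "constant")
  # log transform of the predictor
  xm <- exp(seq(0.1, 2, length.out = 15))
  fit3 <- suppressWarnings(
    bivariate_regression(3 * log(xm) + 2, xm, transform = "log"))
  expect_equal(fit3$slope, 3)
})

test_that("the polynomial comparison equals the closed-form nested F test", {
  set.seed(41)
  x <- rnorm(40)
  y <- x + 0.3 * x^2 + rnorm(40)
  f1 <- lm(y ~ x); f2 <- lm(y ~ x + I(x^2))
  rss1 <- sum(stats::residuals(f1)^2)
  rss2 <- sum(stats::residuals(f2)^2)
  F_closed <- ((rss1 - rss2) / 1) / (rss2 / (40 - 3))
  p_closed <- stats::pf(F_closed, 1, 37, lower.tail = FALSE)
  fit <- bivariate_regression(y, x)
  expect_equal(fit$poly_p, p_closed, tolerance = 1e-12)
})

test_that("bootstrapped regressions: sign recovery, null calibration, determinism", {
  set.seed(51)
  region <- rep(c("NA", "CA", "WA", "GU", "CEA", "SA"), each = 60)
  n <- length(region)
  tab_strong <- tibble::tibble(region = region, x = rnorm(n),
                               y = NA_real_)
  tab_strong$y <- 2 * tab_strong$x + rnorm(n, 0, 0.5)   # SNR >> 1
  bs <- bootstrap_regressions(tab_strong, "y", "x", reps = 60, seed = 3)
  expect_gte(bs$share_positive, 0.95)
  # null slope: ~5% of replicates significant (binomial MC slack)
  tab_null <- tibble::tibble(region = region, x = rnorm(n), y = rnorm(n))
  bs_null <- bootstrap_regressions(tab_null, "y", "x", reps = 400, seed = 5)
  expect_lt(abs(bs_null$share_significant - 0.05), 0.05)
  bs2 <- bootstrap_regressions(tab_strong, "y", "x", reps = 60, seed = 3)
  expect_identical(bs$slopes, bs2$slopes)
})

test_that("interaction model: null interactions stay null, true ones dominate", {
  set.seed(61)
  n <- 400
  tab <- tibble::tibble(
    max_temperature = rnorm(n), temperature_change = rnorm(n),
    annual_precipitation = rnorm(n), precipitation_seasonality = rnorm(n),
    seasonality_change = rnorm(n))
  tab$richness_change <- tab$max_temperature - tab$annual_precipitation +
    rnorm(n)
  fit <- interaction_model(tab)
  ints <- fit$coefficients[grepl(":", fit$coefficients$term), ]
  expect_true(all(abs(ints$t) < 3.5))
  # a pure product signal is picked up with near-perfect fit
  tab2 <- tab
  tab2$richness_change <- scale(tab$max_temperature)[, 1] *
    scale(tab$temperature_change)[, 1]
  fit2 <- suppressWarnings(interaction_model(tab2))
  co2 <- fit2$coefficients
  label <- "max_temperature:temperature_change"
  expect_gt(co2$estimate[co2$term == label], 0.9)
  expect_gt(fit2$r_squared, 0.95)
  # duplicated predictor trips the collinearity guard
  tab3 <- tab
  tab3$seasonality_change <- tab3$precipitation_seasonality
  expect_error(interaction_model(tab3), "collinear|inflation")
})

test_that("hand-rolled VIF agrees with the car package", {
  skip_if_not_installed("car")
  set.seed(71)
  n <- 200
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  X$c <- X$a * 0.8 + rnorm(n, 0, 0.5)
  y <- rnorm(n)
  ours <- vif_check <- forestshift:::vif_check(X)
  theirs <- car::vif(lm(y ~ a + b + c, data = cbind(X, y = y)))
  expect_equal(unname(ours[c("a", "b", "c")]), unname(theirs[c("a", "b", "c")]),
               tolerance = 1e-8)
})
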