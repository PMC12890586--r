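#' One-sample two-sided t-test of richness change
#'
#' Tests whether the mean of `values` differs from zero; 95% confidence
#' interval `mean +/- t_{0.975, n-1} * SE`.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @return List `mean, t, p, ci` (length-2), `df`, `n`.
#' @export
regional_ttest <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values")
  if (sd(values) == 0) stop("zero variance")
  tt <- stats::t.test(values, mu = 0)
  list(mean = unname(tt$estimate), t = unname(tt$statistic),
       p = tt$p.value, ci = unname(tt$conf.int),
       df = unname(tt$parameter), n = length(values))
}

# draw a balanced index set: n_per_region indices from each region,
# without replacement (with replacement if with_replacement)
balanced_sample <- function(region, n_per_region, with_replacement = FALSE) {
  idx_by_region <- split(seq_along(region), region)
  short <- vapply(idx_by_region, length, integer(1)) < n_per_region
  if (!with_replacement && any(short)) {
    stop("region(s) with fewer than ", n_per_region, " plots: ",
         paste(names(idx_by_region)[short], collapse = ", "))
  }
  unlist(lapply(idx_by_region, function(ix) {
    sample(ix, n_per_region, replace = with_replacement)
  }), use.names = FALSE)
}

#' Balanced bootstrap t-test
#'
#' Corrects for uneven plot numbers across regions: each replicate draws
#' `n_per_region` plots per region (without replacement by default), runs a
#' one-sample two-sided t-test on the pooled values, and the replicate means,
#' confidence bounds, t statistics and P values are averaged. With k regions
#' the per-replicate degrees of freedom are `k * n_per_region - 1`.
#'
#' @param values Numeric response (e.g. richness change per plot).
#' @param region Region factor/character, same length as `values`.
#' @param n_per_region Plots drawn per region per replicate (default 30).
#' @param reps Number of replicates (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param with_replacement Sample within regions with replacement?
#' @return List `mean_of_means, mean_ci (length 2), mean_t, mean_p,
#'   share_significant` (share of replicates with `p <= 0.05`; each
#'   replicate is an exact t-test on a random subset, so under a true null
#'   this share has expectation 0.05), `df, reps, n_per_region, seed`.
#' @export
balanced_bootstrap_ttest <- function(values, region, n_per_region = 30,
                                     reps = 1000, seed = NULL,
                                     with_replacement = FALSE) {
  stopifnot(length(values) == length(region))
  if (!is.null(seed)) set.seed(seed)
  k <- length(unique(region))
  n <- k * n_per_region
  df <- n - 1
  tcrit <- qt(0.975, df)
  out <- matrix(NA_real_, nrow = reps, ncol = 5,
                dimnames = list(NULL, c("mean", "lo", "hi", "t", "p")))
  for (r in seq_len(reps)) {
    x <- values[balanced_sample(region, n_per_region, with_replacement)]
    m <- mean(x)
    se <- sd(x) / sqrt(n)
    tstat <- m / se
    out[r, ] <- c(m, m - tcrit * se, m + tcrit * se, tstat,
                  2 * pt(-abs(tstat), df))
  }
  list(mean_of_means = mean(out[, "mean"]),
       mean_ci = c(mean(out[, "lo"]), mean(out[, "hi"])),
       mean_t = mean(out[, "t"]), mean_p = mean(out[, "p"]),
       share_significant = mean(out[, "p"] <= 0.05),
       df = df, reps = reps, n_per_region = n_per_region, seed = seed)
}

#' Bivariate regression with a polynomial check
#'
#' Ordinary least squares of `y` on `x`; optionally also fits
#' `y ~ x + x^2` and compares the two by a nested-model F test (ANOVA); the
#' polynomial is preferred when that test has `p <= 0.05`. A log transform
#' of the predictor is available (used for mortality rate).
#'
#' @param y,x Numeric vectors.
#' @param polynomial_check Compare against the second-order fit?
#' @param transform `"none"` or `"log"` (natural log of `x`; requires
#'   `x > 0`).
#' @return List `slope, intercept, r_squared, adj_r_squared, p` (slope
#'   P value), `polynomial_preferred, poly_p` (nested F P value or `NA`),
#'   `n`, and the linear `fit`.
#' @export
bivariate_regression <- function(y, x, polynomial_check = TRUE,
                                 transform = c("none", "log")) {
  transform <- match.arg(transform)
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (transform == "log") {
    if (any(x <= 0)) stop("log transform requires positive x")
    x <- log(x)
  }
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0) stop("constant predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  poly_p <- NA_real_
  poly_pref <- FALSE
  if (polynomial_check && length(x) >= 4) {
    fit2 <- lm(y ~ x + I(x^2))
    poly_p <- anova(fit, fit2)[2, "Pr(>F)"]
    poly_pref <- is.finite(poly_p) && poly_p <= 0.05
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
       p = sm$coefficients[2, 4],
       polynomial_preferred = poly_pref, poly_p = poly_p,
       n = length(x), fit = fit)
}

#' Balanced bootstrap of a bivariate regression
#'
#' Refits the regression on `reps` balanced subsamples (`n_per_region` plots
#' per region) to check whether the full-dataset slope direction and
#' significance are robust to spatial sampling bias.
#'
#' @param table Analysis table with a `region` column.
#' @param response,predictor Column names.
#' @param reps Number of balanced refits (default 100).
#' @inheritParams balanced_bootstrap_ttest
#' @inheritParams bivariate_regression
#' @return List `slopes, p_values` (length `reps`), `share_positive,
#'   share_significant` (at 0.05), `full` (full-dataset
#'   [bivariate_regression()] result).
#' @export
bootstrap_regressions <- function(table, response, predictor, reps = 100,
                                  n_per_region = 30, seed = NULL,
                                  transform = c("none", "log")) {
  transform <- match.arg(transform)
  if (!is.null(seed)) set.seed(seed)
  full <- bivariate_regression(table[[response]], table[[predictor]],
                               polynomial_check = FALSE, transform = transform)
  slopes <- p_values <- numeric(reps)
  for (r in seq_len(reps)) {
    ix <- balanced_sample(table$region, n_per_region)
    fit <- bivariate_regression(table[[response]][ix], table[[predictor]][ix],
                                polynomial_check = FALSE, transform = transform)
    slopes[r] <- fit$slope
    p_values[r] <- fit$p
  }
  list(slopes = slopes, p_values = p_values,
       share_positive = mean(slopes > 0),
       share_significant = mean(p_values <= 0.05),
       full = full)
}

# variance inflation factors from the correlation matrix of the predictors
vif_check <- function(X, max_vif = Inf) {
  X <- as.matrix(X)
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) stop("constant predictor(s): ",
                       paste(colnames(X)[!keep], collapse = ", "))
  R <- stats::cor(X)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("predictors are collinear (singular correlation matrix)")
  })
  vif <- diag(Rinv)
  if (any(vif >= max_vif)) {
    stop("variance inflation factor >= ", max_vif, " for: ",
         paste(colnames(X)[vif >= max_vif], collapse = ", "))
  }
  vif
}

#' Regression with interacting climate variables
#'
#' Predictors are z-scored before products are formed, so interaction terms
#' are interpretable and main effects are centred. The default interaction
#' set pairs precipitation seasonality with its change and with annual
#' precipitation, annual precipitation with seasonality change, and maximum
#' temperature with temperature change. Collinear predictors trip a
#' variance-inflation guard.
#'
#' @param table Analysis table.
#' @param response Response column name (default `"richness_change"`).
#' @param interactions List of length-2 character vectors naming predictor
#'   pairs.
#' @param max_vif VIF threshold on the main-effect predictors (default 10;
#'   an error names the offending predictors).
#' @return List with the fitted `lm` (`fit`), a tidy `coefficients` tibble,
#'   `r_squared`, `adj_r_squared`, `vif`, and residual diagnostics
#'   (`shapiro_p`, `bp_p` when lmtest is available).
#' @export
interaction_model <- function(table, response = "richness_change",
                              interactions = list(
                                c("precipitation_seasonality", "seasonality_change"),
                                c("precipitation_seasonality", "annual_precipitation"),
                                c("annual_precipitation", "seasonality_change"),
                                c("max_temperature", "temperature_change")),
                              max_vif = 10) {
  main <- unique(unlist(interactions))
  X <- scale(as.matrix(table[, main]))
  vif <- vif_check(X, max_vif)
  dat <- as.data.frame(X)
  dat$.y <- table[[response]]
  terms <- c(main, vapply(interactions, function(pr) paste(pr, collapse = ":"),
                          character(1)))
  fit <- lm(stats::reformulate(terms, ".y"), data = dat)
  sm <- summary(fit)
  shapiro_p <- if (nrow(dat) >= 3 && nrow(dat) <= 5000) {
    stats::shapiro.test(stats::residuals(fit))$p.value
  } else NA_real_
  bp_p <- if (requireNamespace("lmtest", quietly = TRUE)) {
    lmtest::bptest(fit)$p.value
  } else NA_real_
  list(fit = fit,
       coefficients = tibble::tibble(
         term = rownames(sm$coefficients),
         estimate = sm$coefficients[, 1],
         se = sm$coefficients[, 2],
         t = sm$coefficients[, 3],
         p = sm$coefficients[, 4]),
       r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
       vif = vif, shapiro_p = shapiro_p, bp_p = unname(bp_p))
}
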