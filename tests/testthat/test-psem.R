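test_that("component fits: standardized slopes, VIF guard, Pearson identity", {
  set.seed(81)
  d <- tibble::tibble(x = rnorm(50))
  d$y <- 2 * d$x
  fc <- suppressWarnings(fit_component("y", "x", d))
  expect_equal(fc$coefficients$std_estimate, 1)
  # simple-regression standardized slope equals Pearson r exactly
  d2 <- tibble::tibble(x = rnorm(80), y = rnorm(80))
  fc2 <- fit_component("y", "x", d2)
  expect_equal(fc2$coefficients$std_estimate, stats::cor(d2$x, d2$y),
               tolerance = 1e-12)
  d3 <- tibble::tibble(x = rnorm(50))
  d3$z <- d3$x
  d3$y <- rnorm(50)
  expect_error(fit_component("y", c("x", "z"), d3), "collinear|inflation")
})

test_that("the d-separation basis set follows the DAG", {
  # saturated model: no missing edges, empty basis set
  sat <- path_model_spec(list(m = "x", y = c("x", "m")))
  expect_equal(nrow(dsep_basis_set(sat)), 0)
  # chain x -> m -> y: a single claim, x _||_ y | m
  chain <- path_model_spec(list(m = "x", y = "m"))
  claims <- dsep_basis_set(chain)
  expect_equal(nrow(claims), 1)
  expect_equal(claims$dependent, "y")
  expect_equal(claims$independent, "x")
  expect_equal(claims$conditioning[[1]], "m")
  # default model: identification effort is absent from the two demographic
  # components, giving exactly two claims
  def <- dsep_basis_set(path_model_spec())
  expect_equal(nrow(def), 2)
  expect_setequal(def$dependent, c("mortality_rate", "stem_abundance_change"))
  expect_equal(unique(def$independent), "id_effort_change")
})

test_that("Fisher's C combines claim P values with the chi-squared tail", {
  expect_equal(fisher_c(c(1, 1)), list(C = 0, df = 4, p = 1))
  fc <- fisher_c(c(0.5, 0.5))
  expect_equal(fc$C, -2 * log(0.25))
  expect_equal(fc$C, 2.7726, tolerance = 1e-4)
  # closed form for df = 4: p = exp(-C/2) * (1 + C/2)
  expect_equal(fc$p, exp(-fc$C / 2) * (1 + fc$C / 2), tolerance = 1e-12)
  expect_equal(fc$p, 0.5966, tolerance = 1e-4)
  # empty basis set: saturated model fits perfectly
  expect_equal(fisher_c(numeric(0)), list(C = 0, df = 0, p = 1))
  expect_error(fisher_c(c(0.5, 0)), "p > 0")
})

test_that("Fisher's C is additive over concatenated claim sets", {
  set.seed(82)
  p1 <- runif(3)
  p2 <- runif(4)
  a <- fisher_c(p1); b <- fisher_c(p2); ab <- fisher_c(c(p1, p2))
  expect_equal(ab$C, a$C + b$C)
  expect_equal(ab$df, a$df + b$df)
})

test_that("a single group reduces the multigroup fit to plain components", {
  tab <- generate_sem_table(n_per_region = 80, regions = "WA", seed = 5)
  fit <- multigroup_fit(path_model_spec(), tab)
  expect_true(all(fit$paths$constrained))
  ref <- fit_component("richness_change",
                       default_sem_formulas()$richness_change, tab)
  got <- fit$paths[fit$paths$component == "richness_change", ]
  expect_equal(got$estimate, ref$coefficients$estimate, tolerance = 1e-12)
  expect_equal(got$std_estimate, ref$coefficients$std_estimate,
               tolerance = 1e-12)
})

test_that("homogeneous paths are constrained, heterogeneous ones freed", {
  # equal coefficients in all regions: the strong paths stay constrained in
  # >= 90% of simulation replicates at alpha = 0.05
  n_con <- 0
  reps <- 20
  for (s in seq_len(reps)) {
    tab <- generate_sem_table(n_per_region = 40, seed = 100 + s)
    fit <- multigroup_fit(path_model_spec(), tab)
    row <- fit$paths[fit$paths$component == "richness_change" &
                       fit$paths$term == "stem_abundance_change", ]
    n_con <- n_con + as.integer(row$constrained[1])
  }
  expect_gte(n_con / reps, 0.9)
  # one region generated with the opposite sign at high SNR: freed
  tab2 <- generate_sem_table(
    n_per_region = 60,
    region_overrides = list("NA" = list(
      richness_change = c(stem_abundance_change = -0.4))),
    seed = 7)
  fit2 <- multigroup_fit(path_model_spec(), tab2)
  row2 <- fit2$paths[fit2$paths$component == "richness_change" &
                       fit2$paths$term == "stem_abundance_change", ]
  expect_false(any(row2$constrained))
  expect_equal(nrow(row2), 6)   # one estimate per region when free
  expect_lt(row2$estimate[row2$region == "NA"], 0)
})

test_that("standardized coefficients are invariant to affine rescaling", {
  tab <- generate_sem_table(n_per_region = 50, seed = 11)
  fit <- multigroup_fit(path_model_spec(), tab)
  tab2 <- tab
  tab2$mortality_rate <- 3.7 * tab2$mortality_rate + 2
  tab2$max_temperature <- 0.25 * tab2$max_temperature - 40
  tab2$richness_change <- 10 * tab2$richness_change
  fit2 <- multigroup_fit(path_model_spec(), tab2)
  expect_equal(fit2$paths$std_estimate, fit$paths$std_estimate,
               tolerance = 1e-10)
  expect_equal(fit2$paths$constrained, fit$paths$constrained)
  expect_equal(fit2$fisher_c$p, fit$fisher_c$p, tolerance = 1e-10)
})

test_that("constrained-path estimates recover the generating values", {
  tab <- generate_sem_table(n_per_region = 67, seed = 13)   # ~400 rows
  truth <- attr(tab, "truth")$betas
  fit <- multigroup_fit(path_model_spec(), tab)
  tol <- 3 / sqrt(nrow(tab))   # ~3 SEs of a standardized coefficient
  for (resp in names(truth)) {
    for (x in names(truth[[resp]])) {
      row <- fit$paths[fit$paths$component == resp & fit$paths$term == x, ]
      est <- mean(row$std_estimate)
      expect_lt(abs(est - truth[[resp]][[x]]), tol)
    }
  }
})

test_that("removing a truly-zero path keeps the d-separation fit good", {
  forms <- default_sem_formulas()
  forms$richness_change <- setdiff(forms$richness_change,
                                   "precipitation_change")
  spec <- path_model_spec(forms)
  expect_equal(nrow(dsep_basis_set(spec)), 3)   # one new claim
  good <- 0
  for (s in 1:10) {
    tab <- generate_sem_table(n_per_region = 40, seed = 200 + s)
    fit <- multigroup_fit(spec, tab)
    good <- good + as.integer(fit$fisher_c$p > 0.05)
  }
  expect_gte(good, 9)
})

test_that("effect decomposition multiplies significant links and sums pathways", {
  spec <- path_model_spec(list(
    mortality_rate = c("x1", "x2"),
    stem_abundance_change = c("x1", "x2", "mortality_rate"),
    richness_change = c("x1", "x2", "mortality_rate",
                        "stem_abundance_change")))
  path_row <- function(component, term, std, p) {
    tibble::tibble(component = component, term = term, constrained = TRUE,
                   region = "all", estimate = std, std_estimate = std,
                   p = p, interaction_p = NA_real_)
  }
  paths <- dplyr::bind_rows(
    path_row("mortality_rate", "x1", 0.30, 0.001),
    path_row("mortality_rate", "x2", 0.10, 0.20),     # not significant
    path_row("stem_abundance_change", "x1", 0.50, 0.001),
    path_row("stem_abundance_change", "x2", 0.20, 0.01),
    path_row("stem_abundance_change", "mortality_rate", -0.40, 0.001),
    path_row("richness_change", "x1", 0.15, 0.04),
    path_row("richness_change", "x2", 0.05, 0.50),    # not significant
    path_row("richness_change", "mortality_rate", -0.10, 0.01),
    path_row("richness_change", "stem_abundance_change", 0.40, 0.001))
  fit <- structure(list(paths = paths, spec = spec, groups = "all",
                        alpha = 0.05), class = "path_fit")
  dec <- effect_decomposition(fit)
  x1 <- dec[dec$predictor == "x1", ]
  expect_equal(x1$direct, 0.15)
  expect_equal(x1$indirect_via_stem, 0.5 * 0.4)          # 0.20
  expect_equal(x1$indirect_via_mortality, 0.3 * -0.1)    # -0.03
  expect_equal(x1$indirect_via_mortality_then_stem, 0.3 * -0.4 * 0.4)
  expect_equal(x1$total_indirect, 0.2 - 0.03 - 0.048)
  expect_equal(x1$total, x1$direct + x1$total_indirect)
  # any non-significant link zeroes its pathways
  x2 <- dec[dec$predictor == "x2", ]
  expect_equal(x2$direct, 0)                     # p = 0.5
  expect_equal(x2$indirect_via_mortality, 0)     # x2 -> mortality ns
  expect_equal(x2$indirect_via_mortality_then_stem, 0)
  expect_equal(x2$indirect_via_stem, 0.2 * 0.4)  # both links significant
  # mortality's own indirect path runs through stem abundance change
  mo <- dec[dec$predictor == "mortality_rate", ]
  expect_equal(mo$indirect_via_stem, -0.4 * 0.4)
  expect_equal(mo$direct, -0.1)
})

test_that("free significant paths contribute their per-region effects", {
  tab <- generate_sem_table(
    n_per_region = 150,
    region_overrides = list("NA" = list(
      richness_change = c(stem_abundance_change = -0.4))),
    seed = 7)
  fit <- multigroup_fit(path_model_spec(), tab)
  free <- fit$paths[fit$paths$component == "richness_change" &
                      fit$paths$term == "stem_abundance_change", ]
  expect_false(any(free$constrained))
  dec <- effect_decomposition(fit)
  row <- dec[dec$predictor == "stem_abundance_change", ]
  for (g in fit$groups) {
    link <- free[free$region == g, ]
    want <- if (link$p <= 0.05) link$std_estimate else 0
    expect_equal(row$direct[row$region == g], want)
  }
  # the sign-flipped region carries a negative direct effect
  expect_lt(row$direct[row$region == "NA"], -0.2)
  expect_gt(sum(row$direct > 0.2), 3)
})

test_that("pathway arithmetic: stated three-pathway sum", {
  expect_equal(0.20 + (-0.06) + 0.012, 0.152)
  # invariant: total = direct + sum of the three pathways on a fitted model
  tab <- generate_sem_table(n_per_region = 50, seed = 17)
  fit <- multigroup_fit(path_model_spec(), tab)
  dec <- effect_decomposition(fit)
  expect_equal(dec$total,
               dec$direct + dec$indirect_via_stem +
                 dec$indirect_via_mortality +
                 dec$indirect_via_mortality_then_stem)
})
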