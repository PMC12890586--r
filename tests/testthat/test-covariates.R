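mk_climate <- function(plot_id = "P", years = 2000, precip = rep(100, 12),
                       tmax = rep(30, 12)) {
  dplyr::bind_rows(lapply(years, function(y) {
    tibble::tibble(plot_id = plot_id, year = y, month = 1:12,
                   tmax_c = tmax, precip_mm = precip)
  }))
}

test_that("annual summaries: max temperature, precipitation total, CV", {
  a <- annual_summaries(mk_climate(precip = rep(100, 12)))
  expect_equal(a$precip_annual, 1200)
  expect_equal(a$cv_annual, 0)
  expect_equal(a$tmax_annual, 30)
  # CV is scale-invariant
  a2 <- annual_summaries(mk_climate(precip = c(0, 50, rep(100, 10))))
  a3 <- annual_summaries(mk_climate(precip = 2 * c(0, 50, rep(100, 10))))
  expect_equal(a2$cv_annual, a3$cv_annual)
  # one wet month out of twelve: sd = sqrt(120000), mean = 100
  a4 <- annual_summaries(mk_climate(precip = c(rep(0, 11), 1200)))
  expect_equal(a4$cv_annual, 100 * sqrt(120000) / 100, tolerance = 1e-10)
  expect_equal(a4$cv_annual, 346.41, tolerance = 1e-2)
})

test_that("incomplete months are rejected with the plot-year named", {
  cl <- mk_climate(years = 2000:2001)[-3, ]
  expect_error(annual_summaries(cl), "P/2000")
})

test_that("baseline is the window mean and trend the OLS slope", {
  years <- 1979:2010
  vals <- 10 + 0.5 * (years - 1979)
  bt <- baseline_and_trend(years, vals)
  expect_equal(unname(bt["slope"]), 0.5)
  expect_equal(unname(bt["mean"]), mean(vals))
  expect_equal(unname(baseline_and_trend(years, rep(3, length(years)))["slope"]), 0)
  expect_equal(unname(baseline_and_trend(c(2000, 2010), c(1, 2))["slope"]), 0.1)
  # trend equivariance: adding c * year adds c to the slope
  bt2 <- baseline_and_trend(years, vals + 0.2 * years)
  expect_equal(unname(bt2["slope"]), 0.7, tolerance = 1e-10)
})

test_that("climate windows end at each plot's final census year", {
  set.seed(5)
  cl <- dplyr::bind_rows(
    mk_climate("A", 1979:2019, precip = NULL, tmax = NULL) |>
      dplyr::mutate(tmax_c = 28 + 0.05 * (year - 1979) + rnorm(dplyr::n(), 0, 0.2),
                    precip_mm = 150 + rnorm(dplyr::n(), 0, 5)))
  cl_b <- dplyr::mutate(cl, plot_id = "B")
  cov <- climate_covariates(dplyr::bind_rows(cl, cl_b),
                            c(A = 2005.6, B = 2019.2))
  expect_equal(cov$window_end, c(2005, 2019))
  # direct recomputation oracle for plot A
  annA <- annual_summaries(cl)
  annA <- annA[annA$year <= 2005, ]
  oracle <- baseline_and_trend(annA$year, annA$tmax_annual)
  expect_equal(cov$max_temperature[cov$plot_id == "A"], unname(oracle["mean"]))
  expect_equal(cov$temperature_change[cov$plot_id == "A"], unname(oracle["slope"]))
  # different windows on the same series give different baselines
  expect_false(cov$max_temperature[1] == cov$max_temperature[2])
})

test_that("landscape integrity averages tree cover within the radius", {
  uniform <- list(values = matrix(80, 60, 60),
                  lon = seq(-72.95, -67.05, length.out = 60),
                  lat = seq(-2.05, -7.95, length.out = 60), cellsize = 0.1)
  expect_equal(landscape_integrity(uniform, -70, -5, 50), 80)
  # half-plane field, centre on the boundary: ~50, against a 10x finer grid
  half <- function(cellsize) {
    lon <- seq(-73 + cellsize / 2, -67 - cellsize / 2, by = cellsize)
    lat <- seq(-8 + cellsize / 2, -2 - cellsize / 2, by = cellsize)
    list(values = t(vapply(rev(lat), function(la) ifelse(lon < -70, 100, 0),
                           numeric(length(lon)))),
         lon = lon, lat = rev(lat), cellsize = cellsize)
  }
  coarse <- landscape_integrity(half(0.1), -70, -5, 50)
  fine <- landscape_integrity(half(0.01), -70, -5, 50)
  expect_equal(coarse, 50, tolerance = 0.05)
  expect_lt(abs(coarse - fine), 1)
  # radius smaller than one cell returns the containing cell's value
  tiny <- uniform
  tiny$values[30, 30] <- 42
  expect_equal(landscape_integrity(tiny, tiny$lon[30], tiny$lat[30], 0.5), 42)
})

test_that("uncovered discs are rejected with a coverage fraction", {
  grid <- list(values = matrix(80, 10, 10),
               lon = seq(-70.45, -69.55, by = 0.1),
               lat = seq(-4.55, -5.45, by = -0.1), cellsize = 0.1)
  expect_error(landscape_integrity(grid, -70, -5, 200), "%")
})

test_that("tree-cover grids round-trip through the plain-text format", {
  set.seed(6)
  grid <- generate_tree_cover_grid(cellsize = 0.5)
  path <- tempfile(fileext = ".asc")
  write_tree_cover_grid(grid, path)
  back <- read_tree_cover_grid(path)
  expect_equal(back$values, grid$values, tolerance = 1e-10)
  expect_equal(back$lon, grid$lon, tolerance = 1e-10)
  expect_equal(back$lat, grid$lat, tolerance = 1e-10)
})

test_that("the analysis table joins responses and predictors per plot", {
  b <- generate_scenario(scenario_config(plots_per_region = 8,
                                         pool_size = 120, n_stems = 150),
                         seed = 9)
  pipe <- analysis_pipeline(b$census, b$climate, b$landscape)
  expect_equal(nrow(pipe$table), sum(pipe$report$kept))
  expect_true(all(c("richness_change", "stem_abundance_change",
                    "mortality_rate", "max_temperature",
                    "annual_precipitation", "precipitation_seasonality",
                    "temperature_change", "precipitation_change",
                    "seasonality_change", "landscape_integrity",
                    "id_effort_change", "time_frame", "region") %in%
                    names(pipe$table)))
  # disjoint ids produce an empty table with a warning
  expect_warning(
    empty <- build_analysis_table(
      dplyr::mutate(summarize_plots(list()), plot_id = character(0)),
      tibble::tibble(plot_id = "X", max_temperature = 1),
      tibble::tibble(plot_id = "Y", landscape_integrity = 1),
      mk_meta("Z")),
    "no plots")
  expect_equal(nrow(empty), 0)
})
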