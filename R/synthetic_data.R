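#' Log-series random abundances
#'
#' Samples species abundance classes from Fisher's log-series,
#' `P(k) = -x^k / (k * log(1 - x))`, the classic abundance model for
#' tropical tree communities, by inverse-CDF lookup.
#'
#' @param n Number of species.
#' @param x Log-series parameter in (0, 1); larger values give longer tails.
#' @param kmax Truncation point of the support.
#' @return Integer abundances (relative weights).
#' @export
rlogseries <- function(n, x = 0.98, kmax = 10000) {
  stopifnot(x > 0, x < 1)
  k <- seq_len(kmax)
  pmf <- -x^k / (k * log(1 - x))
  sample(k, n, replace = TRUE, prob = pmf)
}

#' Synthetic regional species pool
#'
#' @param n_species Pool size.
#' @param prefix Region tag used in the synthetic genus names.
#' @param x Log-series parameter for the relative-abundance weights.
#' @param n_genera Number of genera the species are spread over.
#' @return Tibble `family, genus, species, weight`.
#' @export
make_species_pool <- function(n_species = 250, prefix = "R", x = 0.98,
                              n_genera = max(10, n_species %/% 5)) {
  genus <- paste0("Genus", prefix, sprintf("%03d", sample.int(n_genera, n_species, replace = TRUE)))
  tibble::tibble(
    family = paste0("Fam", sprintf("%02d", (seq_len(n_species) %% 20) + 1)),
    genus = genus,
    species = paste0("sp", prefix, sprintf("%04d", seq_len(n_species))),
    weight = rlogseries(n_species, x))
}

#' Simulate a census pair for one plot
#'
#' The initial census draws `n_stems` individuals from the pool with
#' probability proportional to the log-series weights. Each stem survives
#' the interval with probability `exp(-mortality * t)`; recruits arrive as a
#' Poisson count with per-capita annual rate `recruitment`. Identification
#' effort is applied by masking a random subset of individuals to genus
#' rank; an individual's identification status is carried across censuses
#' (initial-cohort stems are masked at the initial rate, recruits at the
#' final rate), as identifications in real plot networks are applied to all
#' censuses of a stem.
#'
#' @param pool Species pool from [make_species_pool()].
#' @param n_stems Expected initial stem count.
#' @param mortality,recruitment Per-capita annual rates.
#' @param t Census interval, years.
#' @param plot_id Plot identifier.
#' @param date_initial Decimal year of the initial census.
#' @param id_effort Length-2 vector: percent of individuals identified to
#'   species level among the initial cohort and among recruits.
#' @return `list(initial =, final =)` raw stem tables (unstandardized;
#'   masked stems carry species `"indet"`).
#' @export
generate_census_pair <- function(pool, n_stems = 500, mortality = 0.012,
                                 recruitment = 0.012, t = 10,
                                 plot_id = "P1", date_initial = 2000,
                                 id_effort = c(90, 90)) {
  stopifnot(t > 0, mortality >= 0, recruitment >= 0)
  n0 <- max(1L, rpois(1, n_stems))
  sp <- sample.int(nrow(pool), n0, replace = TRUE, prob = pool$weight)
  mk <- function(idx, tags, masked, date) {
    n <- length(idx)
    tibble::new_tibble(list(
      plot_id = rep(plot_id, n), census_date = rep(date, n), tag = tags,
      family = pool$family[idx], genus = pool$genus[idx],
      species = ifelse(masked, "indet", pool$species[idx]),
      dbh_cm = round(10 + stats::rexp(n, 1 / 12), 1),
      alive = rep(TRUE, n)), nrow = n)
  }
  tags0 <- sprintf("%s-T%05d", plot_id, seq_len(n0))
  masked0 <- runif(n0) > id_effort[1] / 100
  initial <- mk(sp, tags0, masked0, date_initial)
  survives <- rbinom(n0, 1, exp(-mortality * t)) == 1
  n_rec <- rpois(1, n0 * recruitment * t)
  sp_rec <- if (n_rec > 0) {
    sample.int(nrow(pool), n_rec, replace = TRUE, prob = pool$weight)
  } else integer(0)
  tags_rec <- sprintf("%s-R%05d", plot_id, seq_len(n_rec))
  masked_rec <- runif(n_rec) > id_effort[2] / 100
  final <- mk(c(sp[survives], sp_rec), c(tags0[survives], tags_rec),
              c(masked0[survives], masked_rec), date_initial + t)
  list(initial = initial, final = final)
}

#' Simulate a monthly climate series for one plot
#'
#' Monthly maximum temperature is `baseline + trend * (year - year0) +
#' seasonal profile + noise`. Monthly precipitation follows a sinusoidal
#' seasonal profile whose relative amplitude sets the within-year
#' coefficient of variation (`CV ~ 100 * amplitude / sqrt(2)`); the annual
#' total drifts by `precip_trend` per year and the amplitude by
#' `seasonality_trend` per year. Negative monthly precipitation is clamped
#' to zero.
#'
#' @param plot_id Plot identifier.
#' @param years Integer vector of calendar years.
#' @param tmax_base,tmax_trend Baseline (degC) and trend (degC/yr) of
#'   monthly maximum temperature, referenced to the first year.
#' @param tmax_amp Seasonal half-range of tmax, degC.
#' @param precip_annual Baseline annual precipitation, mm.
#' @param precip_trend Annual precipitation trend, mm/yr.
#' @param seasonality_amp Relative seasonal amplitude of precipitation
#'   in `[0, 1)`.
#' @param seasonality_trend Annual change of the relative amplitude, 1/yr.
#' @param noise_tmax,noise_precip Gaussian noise standard deviations.
#' @return Tibble `plot_id, year, month, tmax_c, precip_mm`.
#' @export
generate_climate_series <- function(plot_id, years = 1979:2020,
                                    tmax_base = 30, tmax_trend = 0.03,
                                    tmax_amp = 1.5,
                                    precip_annual = 2200, precip_trend = 0,
                                    seasonality_amp = 0.5,
                                    seasonality_trend = 0,
                                    noise_tmax = 0.3, noise_precip = 8) {
  year0 <- years[1]
  grid <- expand.grid(month = 1:12, year = years)
  dy <- grid$year - year0
  phase <- 2 * pi * (grid$month - 1) / 12
  tmax <- tmax_base + tmax_trend * dy + tmax_amp * cos(phase) +
    rnorm(nrow(grid), 0, noise_tmax)
  amp <- pmax(0, pmin(0.99, seasonality_amp + seasonality_trend * dy))
  pmean <- (precip_annual + precip_trend * dy) / 12
  precip <- pmax(0, pmean * (1 + amp * cos(phase)) +
                   rnorm(nrow(grid), 0, noise_precip))
  tibble::tibble(plot_id = plot_id, year = grid$year, month = grid$month,
                 tmax_c = tmax, precip_mm = precip)
}

#' Synthetic tree-cover grid
#'
#' A smooth random field of percent tree cover on a regular lon/lat grid,
#' for exercising the landscape-integrity extraction.
#'
#' @param lon_range,lat_range Extents in decimal degrees.
#' @param cellsize Cell size in degrees.
#' @param mean_cover Mean percent cover.
#' @param gradient Optional west-to-east linear trend, percent per degree.
#' @param noise_sd Cell noise standard deviation.
#' @return A grid list compatible with [landscape_integrity()].
#' @export
generate_tree_cover_grid <- function(lon_range = c(-75, -65),
                                     lat_range = c(-10, 0),
                                     cellsize = 0.1, mean_cover = 80,
                                     gradient = 0, noise_sd = 5) {
  lon <- seq(lon_range[1] + cellsize / 2, lon_range[2] - cellsize / 2,
             by = cellsize)
  lat <- rev(seq(lat_range[1] + cellsize / 2, lat_range[2] - cellsize / 2,
                 by = cellsize))
  base <- outer(lat, lon, function(la, lo) mean_cover + gradient * (lo - mean(lon)))
  vals <- base + matrix(rnorm(length(base), 0, noise_sd), nrow = nrow(base))
  vals <- matrix(pmax(0, pmin(100, vals)), nrow = nrow(base))
  list(values = vals, lon = lon, lat = lat, cellsize = cellsize)
}

#' Default scenario configuration
#'
#' Study conditions of the synthetic default scenario: six regions of equal
#' plot count, 1-ha plots at tropical-forest stem density, census intervals
#' spanning a decadal monitoring window, and linear ground-truth links from
#' standardized covariates to per-capita demographic rates (higher
#' precipitation seasonality and lower landscape integrity raise mortality;
#' faster warming lowers recruitment). All coefficients are recorded in the
#' generated manifest.
#'
#' @param plots_per_region Plots per region (default 60).
#' @param n_stems Expected stems per 1-ha plot (default 450).
#' @param pool_size Species per regional pool.
#' @param mortality_base,recruitment_base Baseline per-capita annual rates.
#' @param beta_mortality Named vector of mortality-rate effects per SD of
#'   covariate.
#' @param beta_recruitment Named vector of recruitment effects per SD.
#' @param mortality_sd,recruitment_sd Residual plot-level standard deviation
#'   of the per-capita rates (unmodelled site effects: soils, drainage,
#'   local disturbance history), so demographic rates are noisy functions of
#'   the covariates rather than deterministic ones.
#' @param seed Master seed.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(plots_per_region = 60, n_stems = 450,
                            pool_size = 250,
                            mortality_base = 0.015,
                            recruitment_base = 0.015,
                            beta_mortality = c(precipitation_seasonality = 0.005,
                                               landscape_integrity = -0.005),
                            beta_recruitment = c(temperature_change = -0.006),
                            mortality_sd = 0.008,
                            recruitment_sd = 0.008,
                            seed = 1L) {
  structure(as.list(environment()), class = "scenario_config")
}

# rough per-region geography: lon/lat box, elevation range, climate normals
region_geography <- function() {
  tibble::tibble(
    region = REGIONS,
    lon_min = c(-78, -78, -76, -61, -60, -60),
    lon_max = c(-72, -69, -62, -53, -48, -50),
    lat_min = c(0, -17, -12, 1, -8, -13),
    lat_max = c(8, -5, 0, 8, 0, -8),
    elev_min = c(1000, 1000, 100, 50, 30, 100),
    elev_max = c(3500, 3800, 400, 500, 200, 400),
    tmax = c(24, 23, 31, 31, 32, 32),
    precip = c(2400, 1600, 2800, 2400, 2200, 1800),
    seas_amp = c(0.30, 0.55, 0.30, 0.45, 0.55, 0.70))
}

#' Generate a full synthetic scenario
#'
#' Produces every pipeline input with known ground truth: plot metadata,
#' two-census stem tables, monthly climate series consistent with each
#' plot's drawn baselines and trends, and per-plot landscape integrity. The
#' manifest records every true parameter, including the per-plot mortality
#' and recruitment rates implied by the ground-truth coefficient vectors.
#'
#' @param config A [scenario_config()].
#' @param seed Seed; defaults to the config's master seed.
#' @return List `census` ([forest_census()]), `climate`, `landscape`,
#'   `truth` (manifest: config, per-plot true rates and covariates).
#' @export
generate_scenario <- function(config = scenario_config(), seed = config$seed) {
  set.seed(seed)
  geo <- region_geography()
  n_r <- config$plots_per_region
  meta <- dplyr::bind_rows(lapply(seq_len(nrow(geo)), function(i) {
    g <- geo[i, ]
    tibble::tibble(
      plot_id = sprintf("%s_%03d", g$region, seq_len(n_r)),
      region = g$region,
      lon = runif(n_r, g$lon_min, g$lon_max),
      lat = runif(n_r, g$lat_min, g$lat_max),
      elevation_m = runif(n_r, g$elev_min, g$elev_max),
      area_ha = 1.0,
      swamp = FALSE, flooded = FALSE, fire = FALSE,
      large_disturbance = FALSE, taxonomy_issue = FALSE,
      tmax_base = g$tmax + rnorm(n_r, 0, 1.2),
      tmax_trend = rnorm(n_r, 0.028, 0.015),
      precip_base = g$precip + rnorm(n_r, 0, 250),
      precip_trend = rnorm(n_r, -1, 4),
      seas_amp = pmin(0.95, pmax(0.05, g$seas_amp + rnorm(n_r, 0, 0.12))),
      seas_trend = rnorm(n_r, 0.002, 0.002),
      integrity = pmin(100, pmax(20, runif(n_r, 45, 100))))
  }))
  n <- nrow(meta)
  # ground-truth demographic rates: linear in the scenario-standardized covariates
  zcov <- list(
    precipitation_seasonality = as.numeric(scale(meta$seas_amp)),
    landscape_integrity = as.numeric(scale(meta$integrity)),
    temperature_change = as.numeric(scale(meta$tmax_trend)))
  m_true <- rep(config$mortality_base, n) + rnorm(n, 0, config$mortality_sd)
  for (v in names(config$beta_mortality)) {
    m_true <- m_true + config$beta_mortality[[v]] * zcov[[v]]
  }
  r_true <- rep(config$recruitment_base, n) + rnorm(n, 0, config$recruitment_sd)
  for (v in names(config$beta_recruitment)) {
    r_true <- r_true + config$beta_recruitment[[v]] * zcov[[v]]
  }
  m_true <- pmax(0.002, m_true)
  r_true <- pmax(0.002, r_true)
  t_int <- pmin(30, pmax(4.1, stats::rlnorm(n, log(11), 0.4)))
  date0 <- round(runif(n, 1988, 2018 - t_int), 2)
  eff0 <- runif(n, 75, 95)
  eff1 <- pmin(99, pmax(55, eff0 + runif(n, -6, 6)))
  pools <- lapply(seq_len(nrow(geo)), function(i) {
    make_species_pool(config$pool_size, prefix = geo$region[i])
  })
  names(pools) <- geo$region
  stems <- vector("list", n)
  for (i in seq_len(n)) {
    pair <- generate_census_pair(
      pools[[meta$region[i]]], n_stems = config$n_stems,
      mortality = m_true[i], recruitment = r_true[i], t = t_int[i],
      plot_id = meta$plot_id[i], date_initial = date0[i],
      id_effort = c(eff0[i], eff1[i]))
    stems[[i]] <- dplyr::bind_rows(pair$initial, pair$final)
  }
  stems <- dplyr::bind_rows(stems)
  climate <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    generate_climate_series(
      meta$plot_id[i], years = 1979:2021,
      tmax_base = meta$tmax_base[i], tmax_trend = meta$tmax_trend[i],
      precip_annual = meta$precip_base[i], precip_trend = meta$precip_trend[i],
      seasonality_amp = meta$seas_amp[i],
      seasonality_trend = meta$seas_trend[i])
  }))
  landscape <- tibble::tibble(plot_id = meta$plot_id,
                              landscape_integrity = meta$integrity)
  truth <- list(
    seed = seed,
    config = unclass(config),
    nonzero_paths = c(
      "precipitation_seasonality->mortality_rate:+",
      "landscape_integrity->mortality_rate:-",
      "temperature_change->stem_abundance_change:-",
      "mortality_rate->stem_abundance_change:-",
      "stem_abundance_change->richness_change:+"),
    plots = tibble::tibble(plot_id = meta$plot_id, region = meta$region,
                           true_mortality = m_true, true_recruitment = r_true,
                           t = t_int, id_effort_initial = eff0,
                           id_effort_final = eff1))
  census <- forest_census(stems, meta[, META_COLS])
  list(census = census, climate = climate, landscape = landscape,
       truth = truth)
}

#' Generate an analysis table directly from the SEM equations
#'
#' The controlled experiment for the SEM estimator: exogenous covariates are
#' independent standard normals and each endogenous variable is a linear
#' combination with unit marginal variance, so the generating coefficients
#' ARE the true standardized path coefficients. Per-region overrides allow
#' heterogeneous (free) paths.
#'
#' @param n_per_region Rows per region.
#' @param regions Region labels.
#' @param betas Named list of named numeric vectors, one per endogenous
#'   variable of [default_sem_formulas()]; omitted paths are zero.
#' @param region_overrides Optional list `region -> betas-style list`
#'   replacing coefficients in that region only.
#' @param seed Optional seed.
#' @return Tibble with all model columns plus `region`; attribute `truth`
#'   holds the generating coefficients.
#' @export
generate_sem_table <- function(n_per_region = 60, regions = REGIONS,
                               betas = list(
                                 mortality_rate = c(precipitation_seasonality = 0.35,
                                                    landscape_integrity = -0.35),
                                 stem_abundance_change = c(temperature_change = -0.3,
                                                           mortality_rate = -0.35),
                                 richness_change = c(stem_abundance_change = 0.4,
                                                     mortality_rate = -0.2,
                                                     id_effort_change = 0.25)),
                               region_overrides = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- default_sem_formulas()
  n <- n_per_region * length(regions)
  region <- rep(regions, each = n_per_region)
  dat <- as.data.frame(matrix(rnorm(n * length(default_exog())), nrow = n,
                              dimnames = list(NULL, default_exog())))
  for (resp in names(spec)) {
    b_all <- betas[[resp]]
    y <- numeric(n)
    used_var <- numeric(n)
    for (g in regions) {
      b <- b_all
      if (!is.null(region_overrides[[g]][[resp]])) {
        ov <- region_overrides[[g]][[resp]]
        b[names(ov)] <- ov
      }
      ix <- region == g
      mu <- rep(0, sum(ix))
      v <- 0
      for (x in names(b)) {
        mu <- mu + b[[x]] * dat[[x]][ix]
        v <- v + b[[x]]^2
      }
      if (v >= 1) stop("standardized betas imply variance >= 1 for ", resp)
      y[ix] <- mu + rnorm(sum(ix), 0, sqrt(1 - v))
      used_var[ix] <- v
    }
    dat[[resp]] <- y
  }
  dat$region <- region
  out <- tibble::as_tibble(dat)
  attr(out, "truth") <- list(betas = betas, region_overrides = region_overrides)
  out
}

default_exog <- function() {
  c("max_temperature", "annual_precipitation", "precipitation_seasonality",
    "temperature_change", "precipitation_change", "seasonality_change",
    "landscape_integrity", "time_frame", "id_effort_change")
}
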