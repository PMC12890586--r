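#' Annual climate summaries from monthly series
#'
#' For each plot-year with all 12 months present: the annual maximum of
#' monthly maximum temperature, the annual precipitation total, and the
#' precipitation seasonality `CV = 100 * sd / mean` of the 12 monthly
#' totals (sample standard deviation, n - 1).
#'
#' @param climate Tibble with columns `plot_id`, `year`, `month` (1-12),
#'   `tmax_c`, `precip_mm`.
#' @return Tibble `plot_id, year, tmax_annual, precip_annual, cv_annual`.
#' @export
annual_summaries <- function(climate) {
  key <- paste(climate$plot_id, climate$year, sep = "\r")
  n_by <- table(key)
  if (any(n_by != 12)) {
    bad <- sub("\r", "/", names(n_by)[n_by != 12])
    stop("incomplete monthly series for plot-year(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(climate$precip_mm < 0)) stop("negative precipitation")
  # every group has exactly 12 rows: reshape to a 12 x n_years matrix and
  # summarise by column (orders of magnitude faster than per-group code)
  ord <- order(climate$plot_id, climate$year, climate$month)
  tm <- matrix(climate$tmax_c[ord], nrow = 12)
  pp <- matrix(climate$precip_mm[ord], nrow = 12)
  psum <- colSums(pp)
  psd <- sqrt(pmax(0, (colSums(pp^2) - psum^2 / 12) / 11))
  first <- ord[seq(1, length(ord), by = 12)]
  tibble::tibble(
    plot_id = climate$plot_id[first],
    year = climate$year[first],
    tmax_annual = tm[cbind(max.col(t(tm), "first"), seq_len(ncol(tm)))],
    precip_annual = psum,
    cv_annual = 100 * psd / (psum / 12))
}

#' Baseline mean and annual trend of an annual climate variable
#'
#' The baseline is the mean of annual values over the window; the trend is
#' the ordinary least squares slope of the value against calendar year over
#' the same window (both endpoints inclusive).
#'
#' @param years,values Paired annual series.
#' @param window Length-2 integer vector `c(first, last)` calendar year.
#' @return Named numeric `c(mean =, slope =)`.
#' @export
baseline_and_trend <- function(years, values, window = range(years)) {
  keep <- years >= window[1] & years <= window[2]
  years <- years[keep]; values <- values[keep]
  if (length(years) < 2) stop("need at least 2 years in window")
  fit <- lm(values ~ years)
  c(mean = mean(values), slope = unname(coef(fit)[2]))
}

#' Per-plot climate covariates
#'
#' Baselines (maximum temperature, annual precipitation, precipitation
#' seasonality) and their annual trends, over a per-plot window running from
#' `window_start` to the calendar year of that plot's final census
#' (inclusive): lagged climate up to the final census is relevant,
#' post-census climate is not.
#'
#' @param climate Monthly climate tibble (see [annual_summaries()]).
#' @param final_census_year Named vector or tibble (`plot_id`,
#'   `final_census_year`) giving each plot's window end.
#' @param window_start First calendar year of every window (default 1979).
#' @return Tibble with one row per plot: `max_temperature`,
#'   `annual_precipitation`, `precipitation_seasonality`,
#'   `temperature_change`, `precipitation_change`, `seasonality_change`,
#'   `window_start`, `window_end`.
#' @export
climate_covariates <- function(climate, final_census_year, window_start = 1979) {
  if (is.data.frame(final_census_year)) {
    fin <- setNames(final_census_year$final_census_year, final_census_year$plot_id)
  } else {
    fin <- final_census_year
  }
  ann <- annual_summaries(climate)
  ann <- ann[ann$plot_id %in% names(fin), , drop = FALSE]
  ann$window_end <- unname(floor(fin[ann$plot_id]))
  ann <- ann[ann$year >= window_start & ann$year <= ann$window_end, , drop = FALSE]
  ols_slope <- function(x, y) {
    # closed-form OLS slope, vectorised per group
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  out <- ann |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      max_temperature = mean(.data$tmax_annual),
      temperature_change = ols_slope(.data$year, .data$tmax_annual),
      annual_precipitation = mean(.data$precip_annual),
      precipitation_change = ols_slope(.data$year, .data$precip_annual),
      precipitation_seasonality = mean(.data$cv_annual),
      seasonality_change = ols_slope(.data$year, .data$cv_annual),
      window_end = .data$window_end[1], .groups = "drop")
  out$window_start <- window_start
  out
}

#' Read a plain-text tree-cover grid
#'
#' Simple ASCII grid: a header of `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize` lines followed by `nrows` whitespace-separated rows of percent
#' tree cover (top row = northernmost), as written by common GIS exports.
#'
#' @param path File path.
#' @return List with `values` (nrows x ncols matrix), cell-center coordinate
#'   vectors `lon` (by column) and `lat` (by row, decreasing), and `cellsize`.
#' @export
read_tree_cover_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("grid header missing: ", paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (any(m < 0 | m > 100, na.rm = TRUE)) stop("tree cover outside [0, 100]")
  lon <- hdr$xllcorner + (seq_len(hdr$ncols) - 0.5) * hdr$cellsize
  lat <- hdr$yllcorner + (hdr$nrows - seq_len(hdr$nrows) + 0.5) * hdr$cellsize
  list(values = m, lon = lon, lat = lat, cellsize = hdr$cellsize)
}

#' @rdname read_tree_cover_grid
#' @param grid A grid list as returned by `read_tree_cover_grid()`.
#' @export
write_tree_cover_grid <- function(grid, path) {
  hdr <- c(paste("ncols", ncol(grid$values)),
           paste("nrows", nrow(grid$values)),
           paste("xllcorner", format(min(grid$lon) - grid$cellsize / 2, digits = 12)),
           paste("yllcorner", format(min(grid$lat) - grid$cellsize / 2, digits = 12)),
           paste("cellsize", format(grid$cellsize, digits = 12)))
  body <- apply(grid$values, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Landscape integrity around a plot
#'
#' Mean percent tree cover over all grid cells whose centers lie within
#' `radius_km` (great-circle) of the plot location. Errors if the disc is
#' not fully covered by the grid extent, reporting the coverage fraction.
#'
#' @param grid Grid list from [read_tree_cover_grid()].
#' @param lon,lat Plot coordinates, decimal degrees.
#' @param radius_km Buffer radius, default 50 km.
#' @return Percent in `[0, 100]`.
#' @export
landscape_integrity <- function(grid, lon, lat, radius_km = 50) {
  # bounding box of the disc in degrees (lat circle plus margin for lon)
  dlat <- radius_km / 111.2
  dlon <- radius_km / (111.2 * cos(lat * pi / 180))
  covered_lon <- range(grid$lon) + c(-0.5, 0.5) * grid$cellsize
  covered_lat <- range(grid$lat) + c(-0.5, 0.5) * grid$cellsize
  frac <- function(lo, hi, want_lo, want_hi) {
    max(0, min(hi, want_hi) - max(lo, want_lo)) / (want_hi - want_lo)
  }
  cover_frac <- frac(covered_lon[1], covered_lon[2], lon - dlon, lon + dlon) *
    frac(covered_lat[1], covered_lat[2], lat - dlat, lat + dlat)
  if (cover_frac < 1 - 1e-9) {
    stop(sprintf("grid covers only ~%.0f%% of the %g-km disc around (%g, %g)",
                 100 * cover_frac, radius_km, lon, lat))
  }
  use_lon <- which(abs(grid$lon - lon) <= dlon + grid$cellsize)
  use_lat <- which(abs(grid$lat - lat) <= dlat + grid$cellsize)
  cell_lon <- rep(grid$lon[use_lon], each = length(use_lat))
  cell_lat <- rep(grid$lat[use_lat], times = length(use_lon))
  d <- haversine_km(cell_lon, cell_lat, lon, lat)
  inside <- d <= radius_km
  if (!any(inside)) {
    # radius smaller than one cell: take the cell containing the point
    j <- which.min(abs(grid$lon - lon))
    i <- which.min(abs(grid$lat - lat))
    return(grid$values[i, j])
  }
  vals <- grid$values[use_lat, use_lon, drop = FALSE]
  mean(as.vector(vals)[inside])
}

#' Assemble the analysis table
#'
#' One row per analysis plot joining the response and every predictor:
#' plot summaries (richness change, stem abundance change, mortality,
#' identification-effort change, time frame), climate covariates, landscape
#' integrity and metadata (region, coordinates, elevation). Rows with any
#' missing predictor are dropped with a message.
#'
#' @param summaries Output of [summarize_plots()].
#' @param climate Output of [climate_covariates()].
#' @param landscape Tibble `plot_id, landscape_integrity`.
#' @param meta Plot metadata table.
#' @return Tibble, one row per complete plot.
#' @export
build_analysis_table <- function(summaries, climate, landscape, meta) {
  tab <- summaries |>
    dplyr::inner_join(climate, by = "plot_id") |>
    dplyr::inner_join(landscape, by = "plot_id") |>
    dplyr::inner_join(meta[, c("plot_id", "region", "lon", "lat", "elevation_m")],
                      by = "plot_id")
  if (nrow(tab) == 0) {
    warning("no plots shared across summaries, climate, landscape and metadata")
    return(tab)
  }
  predictors <- c("richness_change", "stem_abundance_change", "mortality_rate",
                  "id_effort_change", "time_frame", "max_temperature",
                  "annual_precipitation", "precipitation_seasonality",
                  "temperature_change", "precipitation_change",
                  "seasonality_change", "landscape_integrity", "elevation_m")
  complete <- complete.cases(tab[, predictors])
  if (any(!complete)) {
    message("dropping ", sum(!complete), " plot(s) with missing predictors")
  }
  tab[complete, , drop = FALSE]
}
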