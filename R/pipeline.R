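#' Run the analysis stages from census to analysis table
#'
#' Standardizes taxonomy, applies the stem filters, selects census pairs,
#' groups small plots, computes plot summaries, derives climate and
#' landscape covariates (grouped units receive the mean of their members'
#' covariates) and assembles the analysis table.
#'
#' @param census A [forest_census()] with raw taxonomy.
#' @param climate Monthly climate tibble (see [annual_summaries()]).
#' @param landscape Either a tibble `plot_id, landscape_integrity` or a
#'   tree-cover grid list (then integrity is extracted per plot).
#' @param criteria A [selection_criteria()].
#' @param synonyms Optional synonym table for [standardize_stems()].
#' @param include_palms Forwarded to [apply_stem_filters()].
#' @param radius_km Landscape buffer radius when extracting from a grid.
#' @return List `table` (analysis table), `summaries`, `report` (selection
#'   report), `groups` (small-plot grouping).
#' @export
analysis_pipeline <- function(census, climate, landscape,
                              criteria = selection_criteria(),
                              synonyms = NULL, include_palms = TRUE,
                              radius_km = 50) {
  census$stems <- standardize_stems(census$stems, synonyms)
  census <- apply_stem_filters(census, include_palms = include_palms)
  sel <- apply_selection(census, criteria)
  grp <- group_small_plots(sel$pairs, census$meta, criteria)
  summaries <- summarize_plots(grp$pairs)
  # per-original-plot covariates, then member means for grouped units
  orig_ids <- unique(unlist(c(setdiff(names(grp$pairs), names(grp$groups)),
                              grp$groups)))
  fin_year <- vapply(names(sel$pairs), function(p) {
    floor(mean(sel$pairs[[p]]$final$census_date))
  }, numeric(1))
  clim_cov <- climate_covariates(climate, fin_year[orig_ids])
  if (!is.data.frame(landscape)) {
    meta0 <- census$meta
    landscape <- tibble::tibble(
      plot_id = orig_ids,
      landscape_integrity = vapply(orig_ids, function(p) {
        i <- match(p, meta0$plot_id)
        landscape_integrity(landscape, meta0$lon[i], meta0$lat[i], radius_km)
      }, numeric(1)))
  }
  cov_tab <- dplyr::inner_join(clim_cov, landscape, by = "plot_id")
  for (gid in names(grp$groups)) {
    mem <- cov_tab[cov_tab$plot_id %in% grp$groups[[gid]], , drop = FALSE]
    pooled <- dplyr::summarise(mem, dplyr::across(dplyr::where(is.numeric), mean))
    pooled$plot_id <- gid
    cov_tab <- dplyr::bind_rows(
      cov_tab[!(cov_tab$plot_id %in% grp$groups[[gid]]), , drop = FALSE], pooled)
  }
  table <- build_analysis_table(
    summaries,
    cov_tab[, c("plot_id", "max_temperature", "temperature_change",
                "annual_precipitation", "precipitation_change",
                "precipitation_seasonality", "seasonality_change",
                "window_start", "window_end")],
    cov_tab[, c("plot_id", "landscape_integrity")],
    grp$meta)
  list(table = table, summaries = summaries, report = sel$report,
       groups = grp$groups)
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(paths))
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate -> ingest -> select/summarize -> covariates ->
#' inference -> SEM from a single configuration list (or YAML file), writing
#' stage outputs as TSV, the SEM diagram as DOT and a JSON run manifest with
#' seeds and md5 checksums of every artifact. Stages are pure functions of
#' the declared inputs plus the seed, so a rerun with the same configuration
#' reproduces identical checksums.
#'
#' @param config A list or path to a YAML file. Recognised fields:
#'   `seed`; `scenario` (arguments for [scenario_config()]) or `input`
#'   (paths `census`, `meta`, `climate`, `landscape`); `criteria`
#'   (overrides for [selection_criteria()]); `bootstrap` (`n_per_region`,
#'   `reps`); `stages` (subset of `simulate, select, summarize, covariates,
#'   infer, sem`; default all).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("forestshift_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "select", "summarize",
                                 "covariates", "infer", "sem")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(tab, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tibble::as_tibble(tab), p)
    artifacts <<- c(artifacts, p)
    p
  }
  if ("simulate" %in% stages) {
    sc <- do.call(scenario_config, c(config$scenario, list(seed = seed)))
    bundle <- generate_scenario(sc, seed = seed)
  } else {
    inp <- config$input
    if (is.null(inp$census) || is.null(inp$climate)) {
      stop("config must provide input paths (census, meta, climate, landscape) ",
           "when the simulate stage is disabled")
    }
    bundle <- list(
      census = read_census_table(inp$census, inp$meta),
      climate = readr::read_tsv(inp$climate, show_col_types = FALSE),
      landscape = readr::read_tsv(inp$landscape, show_col_types = FALSE),
      truth = NULL)
  }
  criteria <- do.call(selection_criteria, config$criteria %||% list())
  pipe <- analysis_pipeline(bundle$census, bundle$climate, bundle$landscape,
                            criteria = criteria)
  emit(pipe$report, "selection_report.tsv")
  emit(pipe$summaries, "plot_summaries.tsv")
  emit(pipe$table, "analysis_table.tsv")
  results <- list(table = pipe$table, report = pipe$report)
  if ("infer" %in% stages) {
    bs <- config$bootstrap %||% list()
    set.seed(seed)
    bt <- balanced_bootstrap_ttest(
      pipe$table$richness_change, pipe$table$region,
      n_per_region = bs$n_per_region %||% 30, reps = bs$reps %||% 1000)
    results$bootstrap_ttest <- bt
    emit(tibble::tibble(stat = c("mean_of_means", "ci_low", "ci_high",
                                 "mean_t", "mean_p", "df"),
                        value = c(bt$mean_of_means, bt$mean_ci, bt$mean_t,
                                  bt$mean_p, bt$df)),
         "bootstrap_ttest.tsv")
  }
  if ("sem" %in% stages) {
    fit <- multigroup_fit(path_model_spec(), pipe$table)
    dec <- effect_decomposition(fit)
    results$sem <- fit
    results$effects <- dec
    emit(fit$paths, "sem_paths.tsv")
    emit(dec, "sem_effects.tsv")
    dot <- file.path(out_dir, "sem_diagram.dot")
    write_path_dot(fit, dot)
    artifacts <- c(artifacts, dot)
  }
  manifest <- list(
    package = "forestshift",
    version = as.character(utils::packageVersion("forestshift")),
    seed = seed, stages = stages,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(md5_of(artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
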