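#' Plot selection criteria
#'
#' Thresholds of the eligibility filter and of the small-plot grouping.
#' Boundary semantics: intervals of *less than* `min_interval_yr` are
#' excluded; plots with `min_species - 1` *or fewer* fully identified species
#' are excluded; initial identification effort must be *strictly greater*
#' than `min_id_effort_initial`; the absolute identification-effort change
#' must be *strictly smaller* than `max_id_effort_change`; recruit
#' identification (applied when recruits exceed `recruit_count_trigger`)
#' must be *at least* `min_recruit_id`.
#'
#' @param min_interval_yr Minimum census interval, years.
#' @param min_species Minimum fully identified species in each census
#'   (11 means "more than 10").
#' @param min_id_effort_initial Minimum initial identification effort, %.
#' @param max_id_effort_change Maximum absolute change in identification
#'   effort, percentage points.
#' @param min_recruit_id Minimum % of recruits identified to species.
#' @param recruit_count_trigger Recruit count above which the recruit rule
#'   applies.
#' @param group_area_threshold_ha Plots smaller than this are grouped.
#' @param group_radius_km Grouping radius (great-circle), km.
#' @param group_elevation_band_m Maximum elevation difference between grouped
#'   plots, m.
#' @return A list of class `selection_criteria`.
#' @export
selection_criteria <- function(min_interval_yr = 4,
                               min_species = 11,
                               min_id_effort_initial = 50,
                               max_id_effort_change = 10,
                               min_recruit_id = 50,
                               recruit_count_trigger = 20,
                               group_area_threshold_ha = 0.5,
                               group_radius_km = 7,
                               group_elevation_band_m = 250) {
  out <- as.list(environment())
  stopifnot(all(vapply(out, function(v) is.numeric(v) && v > 0, logical(1))))
  structure(out, class = "selection_criteria")
}

#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371 km, via
#' [geosphere::distHaversine()]. Vectorised over coordinates.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

# identification rules for a candidate (initial, final) pair;
# returns NULL if compliant, else the name of the violated rule
id_rule_violation <- function(initial, final, criteria) {
  ini <- initial[initial$alive, , drop = FALSE]
  fin <- final[final$alive, , drop = FALSE]
  if (nrow(ini) == 0 || nrow(fin) == 0) return("empty_census")
  eff0 <- identification_effort(ini)
  eff1 <- identification_effort(fin)
  if (eff0 <= criteria$min_id_effort_initial) return("id_effort_initial")
  if (abs(eff1 - eff0) >= criteria$max_id_effort_change) return("id_effort_change")
  recruits <- fin[!(fin$tag %in% ini$tag), , drop = FALSE]
  if (nrow(recruits) > criteria$recruit_count_trigger) {
    rec_id <- 100 * sum(recruits$rank == "species") / nrow(recruits)
    if (rec_id < criteria$min_recruit_id) return("recruit_id")
  }
  NULL
}

#' Select the initial and final census of a plot
#'
#' Takes the first census as initial and the last census as final. If the
#' last census violates an identification rule the next-to-last (and so on
#' back to the second) census is tried as the final census. Fails when the
#' initial census itself violates the effort threshold or when no compliant
#' pair exists.
#'
#' @param censuses List of stem tables of one plot, ordered by date
#'   (see internal splitting in [apply_selection()]).
#' @param criteria A [selection_criteria()] object.
#' @return `list(initial =, final =)` on success; otherwise an object of
#'   class `selection_failure` whose `reason` element names the violated
#'   rule.
#' @export
select_censuses <- function(censuses, criteria = selection_criteria()) {
  if (length(censuses) < 2) stop("plot has a single census")
  fail <- function(reason) {
    structure(list(reason = reason), class = "selection_failure")
  }
  initial <- censuses[[1]]
  ini_live <- initial[initial$alive, , drop = FALSE]
  if (nrow(ini_live) == 0 ||
      identification_effort(ini_live) <= criteria$min_id_effort_initial) {
    return(fail("id_effort_initial"))
  }
  for (k in rev(seq_along(censuses))[-length(censuses)]) {
    if (is.null(id_rule_violation(initial, censuses[[k]], criteria))) {
      return(list(initial = initial, final = censuses[[k]]))
    }
  }
  fail("no_compliant_final")
}

#' Apply the plot eligibility filter
#'
#' Drops plots with any disturbance/taxonomy flag, single-census plots,
#' plots violating the identification-effort rules (with final-census
#' fallback), pairs with a census interval of less than
#' `min_interval_yr` years, and plots with fewer than `min_species` fully
#' identified species in either census. Every input plot appears exactly
#' once in the report, with the first failing rule.
#'
#' @param x A `forest_census` (standardized and stem-filtered).
#' @param criteria A [selection_criteria()] object.
#' @return `list(pairs = named list of (initial, final) stem-table pairs,
#'   report = tibble(plot_id, kept, reason))`.
#' @export
apply_selection <- function(x, criteria = selection_criteria()) {
  stopifnot(inherits(x, "forest_census"))
  plots <- x$meta$plot_id
  pairs <- list()
  reasons <- character(length(plots))
  flag_cols <- c("swamp", "flooded", "fire", "large_disturbance", "taxonomy_issue")
  flagged <- apply(as.data.frame(x$meta[, flag_cols]), 1, any, na.rm = TRUE)
  by_plot <- split(seq_len(nrow(x$stems)), x$stems$plot_id)
  for (i in seq_along(plots)) {
    p <- plots[i]
    if (isTRUE(flagged[i])) {
      reasons[i] <- "disturbance_flag"
      next
    }
    s <- x$stems[by_plot[[p]], , drop = FALSE]
    cens <- if (is.null(by_plot[[p]])) list() else {
      dates <- sort(unique(s$census_date))
      lapply(dates, function(d) s[s$census_date == d, , drop = FALSE])
    }
    if (length(cens) < 2) {
      reasons[i] <- "single_census"
      next
    }
    pair <- select_censuses(cens, criteria)
    if (inherits(pair, "selection_failure")) {
      reasons[i] <- pair$reason
      next
    }
    t <- mean(pair$final$census_date) - mean(pair$initial$census_date)
    if (t < criteria$min_interval_yr) {
      reasons[i] <- "short_interval"
      next
    }
    if (species_richness(pair$initial[pair$initial$alive, ]) < criteria$min_species ||
        species_richness(pair$final[pair$final$alive, ]) < criteria$min_species) {
      reasons[i] <- "min_species"
      next
    }
    reasons[i] <- "kept"
    pairs[[p]] <- pair
  }
  report <- tibble::tibble(plot_id = plots, kept = reasons == "kept",
                           reason = reasons)
  list(pairs = pairs, report = report)
}

#' Group small plots into analysis units
#'
#' Plots below the area threshold are merged with compatible sub-threshold
#' companions: within the grouping radius (great-circle), in the same region
#' and within the elevation band. Groups are the connected components of
#' this compatibility graph. Stems are pooled (tags are prefixed with the
#' source plot id so survivor matching stays within plots), areas summed,
#' quantitative metadata averaged, flags OR-combined, and the pooled time
#' frame is the unweighted mean of member intervals. A sub-threshold plot
#' with no companion is kept ungrouped with a warning.
#'
#' @param pairs Named list of census pairs from [apply_selection()].
#' @param meta Plot metadata table covering the plots in `pairs`.
#' @param criteria A [selection_criteria()] object.
#' @return `list(pairs =, meta =, groups = named list of member ids)`.
#' @export
group_small_plots <- function(pairs, meta, criteria = selection_criteria()) {
  meta <- meta[meta$plot_id %in% names(pairs), , drop = FALSE]
  small <- meta[meta$area_ha < criteria$group_area_threshold_ha, , drop = FALSE]
  groups <- list()
  if (nrow(small) >= 2) {
    idx <- t(utils::combn(nrow(small), 2))
    d <- haversine_km(small$lon[idx[, 1]], small$lat[idx[, 1]],
                      small$lon[idx[, 2]], small$lat[idx[, 2]])
    compatible <- d <= criteria$group_radius_km &
      small$region[idx[, 1]] == small$region[idx[, 2]] &
      abs(small$elevation_m[idx[, 1]] - small$elevation_m[idx[, 2]]) <=
        criteria$group_elevation_band_m
    g <- igraph::graph_from_edgelist(
      cbind(small$plot_id[idx[compatible, 1]], small$plot_id[idx[compatible, 2]]),
      directed = FALSE)
    g <- g + igraph::vertices(setdiff(small$plot_id, igraph::V(g)$name))
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
    groups <- members[vapply(members, length, integer(1)) >= 2]
    names(groups) <- vapply(groups, function(m) paste0("grp_", paste(sort(m), collapse = "+")),
                            character(1))
  }
  lonely <- setdiff(small$plot_id, unlist(groups))
  if (length(lonely) > 0) {
    warning("sub-threshold plot(s) with no grouping companion kept ungrouped: ",
            paste(lonely, collapse = ", "))
  }
  new_pairs <- pairs[setdiff(names(pairs), unlist(groups))]
  new_meta <- meta[meta$plot_id %in% names(new_pairs), , drop = FALSE]
  for (gid in names(groups)) {
    mem <- groups[[gid]]
    pool <- function(which) {
      dplyr::bind_rows(lapply(mem, function(p) {
        s <- pairs[[p]][[which]]
        s$tag <- paste(p, s$tag, sep = ":")
        s$plot_id <- gid
        s
      }))
    }
    t_mem <- vapply(mem, function(p) {
      mean(pairs[[p]]$final$census_date) - mean(pairs[[p]]$initial$census_date)
    }, numeric(1))
    new_pairs[[gid]] <- list(initial = pool("initial"), final = pool("final"),
                             t = mean(t_mem))
    mm <- meta[match(mem, meta$plot_id), , drop = FALSE]
    new_meta <- dplyr::bind_rows(new_meta, tibble::tibble(
      plot_id = gid, region = mm$region[1],
      lon = mean(mm$lon), lat = mean(mm$lat),
      elevation_m = mean(mm$elevation_m), area_ha = sum(mm$area_ha),
      swamp = any(mm$swamp), flooded = any(mm$flooded), fire = any(mm$fire),
      large_disturbance = any(mm$large_disturbance),
      taxonomy_issue = any(mm$taxonomy_issue)))
  }
  list(pairs = new_pairs, meta = new_meta, groups = groups)
}
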