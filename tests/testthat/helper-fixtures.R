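# deterministic census builders used across the test files

# one census: n_sp species x reps stems, optionally masked to genus rank.
# n_masked stems (taken from the end) get species "indet"; extra_stems are
# appended verbatim.
mk_census <- function(plot_id, date, n_sp = 12, reps = 2, n_masked = 0,
                      tag_prefix = "T", dbh = 20, genus_pool = 4) {
  n <- n_sp * reps
  sp_ix <- rep(seq_len(n_sp), each = reps)
  species <- paste0("alpha", sp_ix)
  if (n_masked > 0) species[(n - n_masked + 1):n] <- "indet"
  tibble::tibble(
    plot_id = plot_id, census_date = date,
    tag = paste0(tag_prefix, sprintf("%03d", seq_len(n))),
    family = "Lauraceae",
    genus = paste0("Ocotea", ((sp_ix - 1) %% genus_pool) + 1),
    species = species,
    dbh_cm = dbh, alive = TRUE)
}

mk_meta <- function(plot_id, region = "WA", lon = -70, lat = -5,
                    elevation_m = 200, area_ha = 1,
                    swamp = FALSE, flooded = FALSE, fire = FALSE,
                    large_disturbance = FALSE, taxonomy_issue = FALSE) {
  tibble::tibble(plot_id = plot_id, region = region, lon = lon, lat = lat,
                 elevation_m = elevation_m, area_ha = area_ha,
                 swamp = swamp, flooded = flooded, fire = fire,
                 large_disturbance = large_disturbance,
                 taxonomy_issue = taxonomy_issue)
}

with_rank <- function(stems) standardize_stems(stems)

# 12-plot fixture: one violation of each selection rule, two fallback/edge
# cases, and compliant controls. Designed survivor set:
#   P01, P02 (controls), P08 (next-to-last fallback), P12 (boundary interval)
selection_fixture <- function() {
  stems <- list()
  meta <- list()
  add <- function(censuses, m) {
    stems[[length(stems) + 1]] <<- dplyr::bind_rows(censuses)
    meta[[length(meta) + 1]] <<- m
  }
  # P01, P02: fully compliant, 12 species, 10-yr interval
  add(list(mk_census("P01", 1990), mk_census("P01", 2000)), mk_meta("P01"))
  add(list(mk_census("P02", 1990), mk_census("P02", 2000)), mk_meta("P02"))
  # P03: swamp flag
  add(list(mk_census("P03", 1990), mk_census("P03", 2000)),
      mk_meta("P03", swamp = TRUE))
  # P04: single census
  add(list(mk_census("P04", 1990)), mk_meta("P04"))
  # P05: interval 3 yr (< 4)
  add(list(mk_census("P05", 1990), mk_census("P05", 1993)), mk_meta("P05"))
  # P06: only 10 species in the final census ("ten or fewer")
  add(list(mk_census("P06", 1990), mk_census("P06", 2000, n_sp = 10)),
      mk_meta("P06"))
  # P07: initial identification effort 45% (<= 50)
  add(list(mk_census("P07", 1990, n_sp = 20, n_masked = 22),
           mk_census("P07", 2000, n_sp = 20, n_masked = 22)),
      mk_meta("P07"))
  # P08: last census drops effort by 25 points, next-to-last compliant
  add(list(mk_census("P08", 1990), mk_census("P08", 2000),
           mk_census("P08", 2010, n_sp = 20, n_masked = 10)),
      mk_meta("P08"))
  # P09: same violation but only two censuses -> no compliant final
  add(list(mk_census("P09", 1990), mk_census("P09", 2000, n_sp = 20, n_masked = 10)),
      mk_meta("P09"))
  # P10: > 20 recruits of which only 40% identified (recruit rule); overall
  # effort change kept below 10 points by a low-ish initial effort (60%)
  p10_ini <- mk_census("P10", 1990, n_sp = 20, reps = 2, n_masked = 16)
  p10_rec <- mk_census("P10", 2000, n_sp = 25, reps = 1, n_masked = 15,
                       tag_prefix = "R")
  p10_fin <- dplyr::bind_rows(
    dplyr::mutate(p10_ini, census_date = 2000), p10_rec)
  add(list(p10_ini, p10_fin), mk_meta("P10"))
  # P11: fire flag
  add(list(mk_census("P11", 1990), mk_census("P11", 2000)),
      mk_meta("P11", fire = TRUE))
  # P12: interval exactly 4.0 yr (boundary: kept under strict "< 4")
  add(list(mk_census("P12", 1990), mk_census("P12", 1994)), mk_meta("P12"))
  fc <- forest_census(dplyr::bind_rows(stems), dplyr::bind_rows(meta))
  fc$stems <- standardize_stems(fc$stems)
  fc
}

# brute-force rarefaction oracle: average species count over all C(N, n)
# subsets, enumerated explicitly (feasible for N <= 10)
rarefy_enumerate <- function(abundances, n) {
  ids <- rep(seq_along(abundances), abundances)
  subsets <- utils::combn(length(ids), n)
  mean(apply(subsets, 2, function(ix) length(unique(ids[ix]))))
}

# independent haversine implementation (R = 6371 km) used as oracle
haversine_oracle <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(pmin(1, a)))
}
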