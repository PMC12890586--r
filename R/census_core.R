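#' @importFrom rlang .data
#' @importFrom stats anova coef lm pchisq pf pt qt sd setNames rbinom rnorm
#'   rpois runif complete.cases var na.omit quantile
#' @importFrom utils head
NULL

# canonical stem-table columns; long format, one row per stem per census
STEM_COLS <- c("plot_id", "census_date", "tag", "family", "genus", "species",
               "dbh_cm", "alive")
META_COLS <- c("plot_id", "region", "lon", "lat", "elevation_m", "area_ha",
               "swamp", "flooded", "fire", "large_disturbance", "taxonomy_issue")
REGIONS <- c("NA", "CA", "WA", "GU", "CEA", "SA")

#' Forest census object
#'
#' Bundles the long-format stem table (one row per stem per census) with the
#' plot metadata table. All downstream operations (filtering, selection,
#' summarising) consume and return this container.
#'
#' @param stems A data frame with columns `plot_id`, `census_date` (decimal
#'   year), `tag`, `family`, `genus`, `species`, `dbh_cm`, `alive`, and
#'   optionally `rank` (added by [standardize_stems()]).
#' @param meta A data frame with columns `plot_id`, `region`, `lon`, `lat`,
#'   `elevation_m`, `area_ha` and the logical disturbance flags `swamp`,
#'   `flooded`, `fire`, `large_disturbance`, `taxonomy_issue`.
#' @return An object of class `forest_census`.
#' @export
forest_census <- function(stems, meta) {
  stems <- tibble::as_tibble(stems)
  meta <- tibble::as_tibble(meta)
  missing_s <- setdiff(STEM_COLS, names(stems))
  if (length(missing_s) > 0) {
    stop("stem table is missing mandatory column(s): ",
         paste(missing_s, collapse = ", "))
  }
  missing_m <- setdiff(META_COLS, names(meta))
  if (length(missing_m) > 0) {
    stop("metadata table is missing mandatory column(s): ",
         paste(missing_m, collapse = ", "))
  }
  if (any(meta$area_ha <= 0)) stop("plot area must be positive")
  dup <- duplicated(paste(stems$plot_id, stems$census_date, stems$tag,
                          sep = "\r"))
  if (any(dup)) {
    bad <- stems[dup, ]
    stop("duplicated (plot, census, tag) rows, e.g. tag '", bad$tag[1],
         "' in plot '", bad$plot_id[1], "' at ", bad$census_date[1])
  }
  out_of_bounds <- abs(meta$lat) > 30 | meta$lon < -90 | meta$lon > -30
  if (any(out_of_bounds, na.rm = TRUE)) {
    warning(sum(out_of_bounds, na.rm = TRUE),
            " plot(s) have coordinates outside the usual study bounds")
  }
  structure(list(stems = stems, meta = meta), class = "forest_census")
}

#' @export
print.forest_census <- function(x, ...) {
  n_plots <- length(unique(x$meta$plot_id))
  n_cens <- nrow(unique(x$stems[, c("plot_id", "census_date")]))
  cat("<forest_census> ", n_plots, " plots, ", n_cens, " censuses, ",
      nrow(x$stems), " stem records\n", sep = "")
  invisible(x)
}

#' Convert calendar dates to decimal years
#'
#' Numeric input is returned unchanged (already decimal years); character
#' input is parsed either as a decimal year (`"2015.5"`) or as an ISO date
#' (`"2015-07-02"`), the latter converted using day-of-year over year length.
#'
#' @param x Numeric or character vector of dates.
#' @return Numeric vector of decimal years.
#' @export
decimal_year <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  needs_date <- is.na(out) & !is.na(x)
  if (any(needs_date)) {
    d <- as.Date(x[needs_date], optional = TRUE)
    if (anyNA(d)) stop("unparseable census date(s): ",
                       paste(head(x[needs_date][is.na(d)], 3), collapse = ", "))
    yr <- as.integer(format(d, "%Y"))
    doy <- as.integer(format(d, "%j")) - 1L
    ylen <- ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366, 365)
    out[needs_date] <- yr + doy / ylen
  }
  out
}

default_morpho_pattern <- function() "^sp\\.?\\s*[0-9]*$|^[0-9]+$"

is_indet_token <- function(x) {
  is.na(x) | grepl("^\\s*$", x) |
    grepl("^indet(\\.|erminate[ad]?)?$", x, ignore.case = TRUE)
}

#' Standardize a raw taxon name
#'
#' Applies a synonym table, demotes morphospecies codes (e.g. `"Ocotea sp2"`)
#' to genus rank, and classifies fully unidentified records as indeterminate.
#' Morphospecies codes never survive standardization: any epithet matching
#' `morpho_pattern` is mapped to genus rank ("Genus indet").
#'
#' @param raw_name Character vector of binomials (`"Genus epithet"`); a bare
#'   genus is treated as `"Genus indet"`.
#' @param synonyms Optional synonym table: a named character vector or a
#'   two-column data frame (`raw`, `accepted`) mapping raw binomials to
#'   accepted ones. Applied before morphospecies detection.
#' @param morpho_pattern Regex (case-insensitive) identifying morphospecies
#'   epithets; default covers `sp`, `sp1`, `sp. 2` and all-numeric codes.
#' @return A tibble with columns `genus`, `epithet`, `rank`
#'   (`"species"`, `"genus"` or `"indet"`). Idempotent.
#' @examples
#' standardize_taxon("Ocotea sp2")        # genus rank
#' standardize_taxon("Ocotea javitensis") # species rank
#' @export
standardize_taxon <- function(raw_name, synonyms = NULL,
                              morpho_pattern = default_morpho_pattern()) {
  stopifnot(is.character(raw_name) || is.factor(raw_name))
  raw_name <- trimws(as.character(raw_name))
  if (any(!nzchar(raw_name) & !is.na(raw_name))) stop("raw_name must be non-empty")
  if (!is.null(synonyms)) {
    if (is.data.frame(synonyms)) {
      syn <- setNames(as.character(synonyms[[2]]), as.character(synonyms[[1]]))
    } else {
      syn <- synonyms
    }
    hit <- raw_name %in% names(syn)
    raw_name[hit] <- unname(syn[raw_name[hit]])
  }
  genus <- sub("\\s.*$", "", raw_name)
  epithet <- ifelse(grepl("\\s", raw_name),
                    trimws(sub("^\\S+\\s+", "", raw_name)), NA_character_)
  classify_taxon(genus, epithet, morpho_pattern)
}

classify_taxon <- function(genus, epithet,
                           morpho_pattern = default_morpho_pattern()) {
  genus_bad <- is_indet_token(genus)
  ep_indet <- is_indet_token(epithet)
  ep_morpho <- !ep_indet &
    grepl(morpho_pattern, trimws(ifelse(is.na(epithet), "", epithet)),
          ignore.case = TRUE)
  rank <- ifelse(genus_bad, "indet",
                 ifelse(ep_indet | ep_morpho, "genus", "species"))
  tibble::tibble(
    genus = ifelse(rank == "indet", NA_character_, genus),
    epithet = ifelse(rank == "species", epithet, NA_character_),
    rank = rank
  )
}

#' Standardize taxonomy across a stem table
#'
#' Vectorised application of [standardize_taxon()] to the `genus` and
#' `species` columns of a stem table; adds/overwrites a `rank` column and
#' rewrites `genus`/`species` to their standardized form.
#'
#' @param stems A stem table (see [forest_census()]).
#' @inheritParams standardize_taxon
#' @return The stem table with standardized `genus`, `species` and `rank`.
#' @export
standardize_stems <- function(stems, synonyms = NULL,
                              morpho_pattern = default_morpho_pattern()) {
  raw <- ifelse(is_indet_token(stems$genus), "Indet indet",
                paste(stems$genus,
                      ifelse(is_indet_token(stems$species), "indet",
                             stems$species)))
  # standardize distinct names once, then index back
  u <- unique(raw)
  std_u <- standardize_taxon(u, synonyms, morpho_pattern)
  ix <- match(raw, u)
  stems$genus <- std_u$genus[ix]
  stems$species <- std_u$epithet[ix]
  stems$rank <- std_u$rank[ix]
  stems
}

#' Filter stems to the analysis protocol
#'
#' Removes stems below the diameter threshold, the herbaceous families
#' Cyclanthaceae and Araceae, palms (Arecaceae) when `include_palms = FALSE`,
#' and fully unidentified (indeterminate-rank) individuals. Genus-rank stems
#' are retained: they count toward stem totals and genus-level richness but
#' not species richness.
#'
#' @param x A `forest_census` or a stem table with a `rank` column.
#' @param include_palms Keep Arecaceae? Default `TRUE` (palms measured in all
#'   censuses are part of the analysis).
#' @param min_dbh_cm Minimum diameter at breast height, cm. Default 10.
#' @return Object of the same type with offending stems removed. Idempotent;
#'   never increases stem count.
#' @export
apply_stem_filters <- function(x, include_palms = TRUE, min_dbh_cm = 10) {
  if (inherits(x, "forest_census")) {
    x$stems <- apply_stem_filters(x$stems, include_palms, min_dbh_cm)
    return(x)
  }
  stems <- x
  if (!"rank" %in% names(stems)) stop("run standardize_stems() first (no rank column)")
  drop_fam <- c("Cyclanthaceae", "Araceae", if (!include_palms) "Arecaceae")
  keep <- stems$dbh_cm >= min_dbh_cm &
    !(stems$family %in% drop_fam) &
    stems$rank != "indet"
  stems[keep, , drop = FALSE]
}

#' Identification effort of a census
#'
#' Percentage of stems identified to species level.
#'
#' @param stems Stem table of one plot-census (non-empty, with `rank`).
#' @return Percent in `[0, 100]`.
#' @export
identification_effort <- function(stems) {
  if (nrow(stems) == 0) stop("no stems")
  100 * sum(stems$rank == "species") / nrow(stems)
}

#' Read / write census tables
#'
#' Long-format delimited text, one row per stem per census. The census file
#' has columns `plot_id, census_date, tag, family, genus, species, dbh_cm,
#' alive` (plus `rank` if previously standardized); the metadata file has
#' `plot_id, region, lon, lat, elevation_m, area_ha, swamp, flooded, fire,
#' large_disturbance, taxonomy_issue`. The round trip is lossless.
#'
#' @param census_path,meta_path Paths to the stem and metadata tables.
#' @param delim Field delimiter, default tab.
#' @return A [forest_census()] object.
#' @export
read_census_table <- function(census_path, meta_path, delim = "\t") {
  # na = "": the Northern Andes region code is the literal string "NA"
  stems <- readr::read_delim(census_path, delim = delim, show_col_types = FALSE,
                             progress = FALSE, na = "")
  meta <- readr::read_delim(meta_path, delim = delim, show_col_types = FALSE,
                            progress = FALSE, na = "")
  missing_s <- setdiff(STEM_COLS, names(stems))
  if (length(missing_s) > 0) {
    stop("census file is missing mandatory column(s): ",
         paste(missing_s, collapse = ", "))
  }
  stems$census_date <- decimal_year(stems$census_date)
  stems$tag <- as.character(stems$tag)
  stems$alive <- as.logical(stems$alive)
  for (col in c("swamp", "flooded", "fire", "large_disturbance", "taxonomy_issue")) {
    if (col %in% names(meta)) meta[[col]] <- as.logical(meta[[col]])
  }
  forest_census(stems, meta)
}

#' @rdname read_census_table
#' @param x A `forest_census` object.
#' @export
write_census_table <- function(x, census_path, meta_path, delim = "\t") {
  stopifnot(inherits(x, "forest_census"))
  readr::write_delim(x$stems, census_path, delim = delim, na = "")
  readr::write_delim(x$meta, meta_path, delim = delim, na = "")
  invisible(c(census = census_path, meta = meta_path))
}

# split a stem table into per-census tables for one plot, ordered by date
plot_censuses <- function(stems, plot) {
  s <- stems[stems$plot_id == plot, , drop = FALSE]
  dates <- sort(unique(s$census_date))
  lapply(dates, function(d) s[s$census_date == d, , drop = FALSE])
}
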