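#' Species richness of a census
#'
#' Number of distinct fully identified species: distinct (genus, epithet)
#' pairs among species-rank stems. Genus-rank stems (including demoted
#' morphospecies) do not count.
#'
#' @param stems Stem table of one plot-census (standardized, filtered).
#' @return Non-negative integer count.
#' @export
species_richness <- function(stems) {
  ix <- stems$rank == "species"
  length(unique(paste(stems$genus[ix], stems$species[ix])))
}

#' Genus richness of a census
#'
#' Distinct genera among stems identified at least to genus level
#' (species-rank and genus-rank stems, i.e. morphospecies included).
#'
#' @inheritParams species_richness
#' @export
genus_richness <- function(stems) {
  g <- stems$genus[stems$rank %in% c("species", "genus")]
  length(unique(g[!is.na(g)]))
}

#' Annual proportional richness change
#'
#' `((SP_final - SP_initial) / SP_initial * 100) / t`, in percent per year;
#' positive values are gains. The same formula serves genus richness and
#' rarefied richness change.
#'
#' @param sp_initial,sp_final Species counts at the initial and final census.
#' @param t Census interval in years.
#' @return Percent per year.
#' @export
richness_change <- function(sp_initial, sp_final, t) {
  stopifnot(all(t > 0))
  if (any(sp_initial <= 0)) stop("sp_initial must be positive")
  ((sp_final - sp_initial) / sp_initial * 100) / t
}

#' Annual proportional stem abundance change
#'
#' `((n_f - n_0) / n_0 * 100) / t`, percent per year.
#'
#' @param n0,nf Live stem counts at the initial and final census.
#' @param t Census interval in years.
#' @export
stem_abundance_change <- function(n0, nf, t) {
  stopifnot(all(t > 0))
  if (any(n0 <= 0)) stop("n0 must be positive")
  ((nf - n0) / n0 * 100) / t
}

#' Interval-corrected annual mortality rate
#'
#' `mu = ((ln(n0) - ln(ns)) / t * 100) * t^0.08`, percent per year, where
#' `ns` is the number of initial stems that survive the interval. The
#' `t^0.08` factor is the standard correction for the downward bias of
#' ln-ratio mortality estimates over longer census intervals. At `t = 1` the
#' corrected rate equals the uncorrected one.
#'
#' @param n0 Initial live stems (`n0 >= ns`).
#' @param ns Surviving stems. `ns = 0` yields `NA` with a warning (rate
#'   undefined; exclude from models).
#' @param t Census interval in years.
#' @export
mortality_rate <- function(n0, ns, t) {
  stopifnot(all(t > 0), all(n0 >= ns))
  n <- max(length(n0), length(ns), length(t))
  n0 <- rep_len(n0, n); ns <- rep_len(ns, n); t <- rep_len(t, n)
  out <- rep(NA_real_, n)
  ok <- ns > 0
  if (any(!ok)) warning(sum(!ok), " plot(s) with zero survivors: mortality undefined")
  out[ok] <- ((log(n0[ok]) - log(ns[ok])) / t[ok] * 100) * t[ok]^0.08
  out
}

#' Expected species richness under individual-based rarefaction
#'
#' Closed-form hypergeometric expectation of the species count in a random
#' draw of `n` individuals without replacement:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`.
#' Deterministic (no resampling); computed on log-binomials for stability.
#'
#' @param abundances Positive integer vector of per-species abundances.
#' @param n Draw size, `1 <= n <= sum(abundances)`.
#' @return Expected species count (numeric).
#' @export
rarefied_richness <- function(abundances, n) {
  abundances <- abundances[abundances > 0]
  N <- sum(abundances)
  stopifnot(length(abundances) > 0, n >= 1, n <= N)
  p_absent <- exp(lchoose(N - abundances, n) - lchoose(N, n))
  p_absent[N - abundances < n] <- 0
  sum(1 - p_absent)
}

#' Rarefied richness change of a census pair
#'
#' Both censuses are rarefied to the smaller of the two stem totals, then the
#' usual proportional change formula is applied. Used to check that richness
#' change is not a pure artefact of changing stem numbers.
#'
#' @param initial,final Stem tables of the two censuses (standardized,
#'   filtered).
#' @param t Census interval in years.
#' @export
rarefied_richness_change <- function(initial, final, t) {
  a0 <- species_abundances(initial)
  a1 <- species_abundances(final)
  n <- min(sum(a0), sum(a1))
  richness_change(rarefied_richness(a0, n), rarefied_richness(a1, n), t)
}

# per-species abundance vector of species-rank stems
species_abundances <- function(stems) {
  sp <- stems[stems$rank == "species", , drop = FALSE]
  if (nrow(sp) == 0) return(integer(0))
  as.integer(table(paste(sp$genus, sp$species)))
}

#' Shannon and inverse-Simpson diversity of a census
#'
#' Computed on species-rank abundances via [vegan::diversity()]:
#' `H = -sum p_i log p_i` and `1 / sum p_i^2`.
#'
#' @inheritParams species_richness
#' @return Named numeric vector `c(shannon = , inv_simpson = )`.
#' @export
diversity_indices <- function(stems) {
  a <- species_abundances(stems)
  if (length(a) == 0) return(c(shannon = NA_real_, inv_simpson = NA_real_))
  c(shannon = unname(vegan::diversity(a, index = "shannon")),
    inv_simpson = unname(vegan::diversity(a, index = "invsimpson")))
}

#' Per-plot summary statistics for a selected census pair
#'
#' Computes every per-plot quantity used downstream: species and genus
#' richness at both censuses, stem counts, survivors (stems whose tag is
#' present and alive in both censuses), richness change, stem abundance
#' change, interval-corrected mortality, identification-effort change and
#' the census time frame.
#'
#' @param initial,final Stem tables of the selected initial and final census
#'   of one analysis plot (standardized and filtered; only live stems are
#'   counted).
#' @param plot_id Identifier stored in the output row.
#' @param t Census interval override in years (used for grouped units, whose
#'   time frame is the mean of member intervals); computed from census dates
#'   when `NULL`.
#' @return One-row tibble (see fields above).
#' @export
summarize_plot <- function(initial, final, plot_id = initial$plot_id[1],
                           t = NULL) {
  ini <- initial[initial$alive, , drop = FALSE]
  fin <- final[final$alive, , drop = FALSE]
  if (is.null(t)) t <- mean(fin$census_date) - mean(ini$census_date)
  if (!is.finite(t) || t <= 0) stop("census interval must be positive")
  n0 <- nrow(ini)
  nf <- nrow(fin)
  ns <- sum(ini$tag %in% fin$tag)
  sp0 <- species_richness(ini)
  sp1 <- species_richness(fin)
  eff0 <- identification_effort(ini)
  eff1 <- identification_effort(fin)
  tibble::new_tibble(list(
    plot_id = plot_id,
    sp_initial = sp0, sp_final = sp1,
    g_initial = genus_richness(ini), g_final = genus_richness(fin),
    n0 = n0, nf = nf, ns = ns,
    t = t,
    richness_change = if (sp0 > 0) richness_change(sp0, sp1, t) else NA_real_,
    stem_abundance_change = stem_abundance_change(n0, nf, t),
    mortality_rate = suppressWarnings(mortality_rate(n0, ns, t)),
    id_effort_initial = eff0,
    id_effort_final = eff1,
    id_effort_change = eff1 - eff0,
    time_frame = t
  ), nrow = 1L)
}

#' Summaries for every plot of a selected census-pair set
#'
#' @param pairs A named list of `list(initial =, final =)` stem-table pairs,
#'   as produced by [apply_selection()].
#' @return Tibble with one [summarize_plot()] row per plot.
#' @export
summarize_plots <- function(pairs) {
  dplyr::bind_rows(lapply(names(pairs), function(id) {
    summarize_plot(pairs[[id]]$initial, pairs[[id]]$final, plot_id = id,
                   t = pairs[[id]]$t)
  }))
}
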