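---
title: "Methods: quantifying and explaining tree richness change in permanent forest plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and explaining tree richness change in permanent forest plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestshift)
```

## The problem

Permanent forest inventory plots — censused repeatedly over decades, every
stem with diameter at breast height (DBH) of at least 10 cm tagged and
identified — are the only direct record of how tropical tree diversity is
responding to climate and landscape change. `forestshift` implements a
complete analysis chain for such plot networks: census ingestion and
taxonomic standardization, eligibility filtering, per-plot diversity and
demographic statistics, climate and landscape covariates, region-balanced
bootstrap inference, and a multigroup piecewise structural equation model
(SEM) that separates direct climate effects on richness change from effects
mediated by demography. Because real plot compilations are typically
access-restricted, the package ships a synthetic-data generator with known
ground truth, so every stage — and the SEM estimator in particular — can be
validated end to end.

## Per-plot statistics

For each analysis plot we use the first and last usable census, `t` years
apart. With `SP` the number of fully identified species (distinct
genus–epithet pairs among species-rank stems) the annual richness change is

    richness_change = ((SP_final - SP_initial) / SP_initial * 100) / t  [% / yr]

We use the gain-positive orientation (final minus initial) so that positive
values mean species accumulation; all figures and downstream signs follow
this convention. Stem abundance change is the analogous quantity on live
stem counts. The annual mortality rate uses the ln-ratio estimator with the
standard interval-length correction,

    mu = ((ln n0 - ln ns) / t * 100) * t^0.08  [% / yr]

where `ns` counts initial stems whose tag is still alive in the final
census. The exponent 0.08 is the conventional correction for the downward
bias of ln-ratio mortality over long intervals; at `t = 1` it changes
nothing. `ns = 0` leaves the rate undefined (`NA` with a warning) and the
plot is excluded from models.

Individual-based rarefaction uses the closed-form hypergeometric
expectation `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`, evaluated on
log-binomials — deterministic, no resampling. `rarefied_richness_change()`
rarefies both censuses to the smaller stem total before applying the change
formula; comparing it with the raw change checks that richness trends are
not a pure artefact of changing stem numbers. Shannon and inverse-Simpson
indices are delegated to `vegan::diversity()`.

## Taxonomy and identification effort

Morphospecies codes (`"Ocotea sp2"`, numeric codes) are demoted to genus
rank during standardization and never survive it; fully unidentified stems
are removed from the data entirely; genus-rank stems count toward stem
totals and genus richness but not species richness. Identification effort
is the percent of stems identified to species level; its change between
censuses is carried into every model as a sampling covariate, because more
identification mechanically reveals more species.

## Plot eligibility and grouping

`selection_criteria()` encodes the eligibility filter with explicit
boundary semantics: census intervals of *less than* 4 years are excluded
(4.00 is kept); plots with ten *or fewer* fully identified species in
either census are excluded; the initial identification effort must be
*strictly greater* than 50%; the absolute effort change must be *strictly
smaller* than 10 percentage points; and when a plot has more than 20
recruits, at least 50% of them must be identified to species. If the last
census violates an identification rule, the next-to-last census is tried as
the final census before the plot is dropped. Plots flagged as swamp,
seasonally flooded, burnt, disturbed or taxonomically problematic are
removed first, and the selection report records the first rule that fired
for every input plot.

Plots smaller than 0.5 ha are pooled with compatible companions within a
7-km great-circle radius (haversine, R = 6371 km) — same region, elevation
within 250 m — using connected components of the compatibility graph. Stems
are pooled, areas summed, quantitative metadata averaged, and the pooled
time frame is the unweighted mean of member intervals. The identification
and interval rules are evaluated per plot before grouping; because pooled
efforts and intervals are (weighted) means of compliant member values, the
pooled unit inherits compliance.

## Climate and landscape covariates

From monthly series of maximum temperature and precipitation we compute,
per plot-year, the annual maximum of monthly maximum temperature, the
precipitation total and the precipitation seasonality
`CV = 100 * sd / mean` over the 12 monthly totals (sample standard
deviation; the baseline seasonality is the mean of within-year CVs, not the
CV of the pooled series). Baselines are means and trends are OLS slopes
against calendar year over a per-plot window from 1979 to the calendar year
of that plot's final census, both endpoints inclusive — lagged climate up to
the census matters, post-census climate does not. Landscape integrity is
the mean percent tree cover over all grid cells whose centers fall within
50 km of the plot, read from a plain-text regular lon/lat grid; elevation is
consumed as a metadata column.

## Inference

Because plot numbers differ strongly among the six biogeographic regions
(Northern/Central Andes, Western/Central-Eastern/Southern Amazon, Guyana
Shield), the combined-area test is a balanced bootstrap: each of 1000
replicates draws 30 plots per region without replacement, runs a one-sample
two-sided t-test (df = 6 x 30 - 1 = 179), and the replicate means,
confidence bounds, t statistics and P values are averaged. The procedure
targets the unweighted mean of regional means rather than the pooled mean.
Each replicate is an exact t-test on a random subset, so the share of
significant replicates (`share_significant`) has expectation 0.05 under a
true null — this is the size quantity the calibration tests monitor;
the *averaged* P value is a deliberately smoothed summary and is far more
conservative as a decision rule.

Bivariate regressions optionally compare a second-order polynomial against
the linear fit by a nested-model F test (preferred at `p <= 0.05`);
mortality enters bivariate regressions log-transformed. The same balanced
subsampling reruns each regression 100 times to check that slope direction
and significance are robust to the spatial imbalance of plots. The
interaction model z-scores predictors before forming the four default
climate products and refuses collinear designs via a variance-inflation
guard computed from the predictor correlation matrix.

## The multigroup piecewise SEM

The path model is fitted as three component OLS regressions along a causal
DAG: mortality rate on six climate covariates, landscape integrity and time
frame; stem abundance change on the same plus mortality; and richness
change on all of those plus identification-effort change and stem abundance
change (11 predictors). Elevation is excluded (collinear with maximum
temperature); identification-effort change predicts only richness change,
since a sampling artefact cannot cause demography — a restriction the
directed-separation tests then probe. Mortality enters the SEM
untransformed for interpretability.

For each path, heterogeneity across regions is tested with a nested-model F
test of the path-by-region interaction (full set of region dummies, joint
test, alpha = 0.05). Non-significant interactions leave the path
*constrained*: one pooled coefficient (from the component fit with region
intercepts) reported for all regions. Significant interactions free the
path: per-region component fits are reported. Standardized coefficients are
`beta * sd(x) / sd(y)` with pooled standard deviations for constrained
paths and within-region ones for free paths; for a single-predictor model
this equals the Pearson correlation exactly.

The directed-separation basis set contains one claim per non-adjacent
variable pair with an endogenous member (exogenous–exogenous covariances
are free): the downstream variable is regressed on the other variable plus
its own parents (plus region intercepts), and the independence P values are
combined as Fisher's `C = -2 * sum(log p)`, chi-squared with `2k` degrees of
freedom; `p > 0.05` indicates the missing edges are consistent with the
data. An empty basis set (saturated model) is defined as `C = 0, p = 1`.

Effects on richness change are decomposed per predictor and region into a
direct effect (its standardized coefficient in the richness component, when
`p <= 0.05`, else 0) and three indirect pathways — via stem abundance
change, via mortality, and via mortality-then-stem-abundance — each the
product of its standardized links, computed only when *every* link is
significant and contributing exactly 0 otherwise. Constrained paths
contribute their pooled estimate to every region. A path constrained but
non-significant is reported with its pooled estimate and P value rather
than hard-zeroed.

## The synthetic-data generator

`generate_scenario()` emulates the study conditions end to end: six regions
of 60 one-hectare plots with region-typical climate normals, elevations and
coordinates; regional species pools of 250 species with Fisher log-series
relative abundances (the classic tropical tree abundance model); ~450
initial stems per plot; census intervals log-normal around 11 years
(truncated to at least 4); monthly climate with trend, sinusoidal
seasonality and Gaussian noise, generated from each plot's drawn baselines
so the covariate stage must *recover* them; and per-plot landscape
integrity. Ground truth enters through per-capita demographic rates that
are linear in scenario-standardized covariates: higher precipitation
seasonality and lower landscape integrity raise mortality, faster warming
lowers recruitment, and each rate carries residual plot-level noise
(SD 0.008/yr) representing unmodelled site effects — without it demographic
rates would be deterministic functions of two covariates, which no field
network exhibits and which would make the component regressions collinear.
Stems then die by Bernoulli survival `exp(-m t)` and recruits arrive as a
Poisson stream, so the mortality-to-stem-change and stem-change-to-richness
paths arise *mechanically*, exactly as they do in real censuses.
Identification status is assigned per individual and carried across
censuses, as in real plot networks where identifications are applied
retroactively.

Because those mechanical links make the implied standardized path
coefficients non-analytic, the generator has a second, table-level mode:
`generate_sem_table()` draws the analysis table directly from the SEM's
linear equations with unit-variance variables, so the generating betas
*are* the true standardized coefficients. The census-level scenario
validates end-to-end sign recovery; the table-level generator validates
estimator accuracy (constrained-path estimates within Monte-Carlo error of
truth) and resampling size under an exact null.

What the generator does not emulate — and what passing tests therefore do
not establish about real data: spatial autocorrelation of climate and
demography, gap-dynamics coupling of mortality and recruitment (available
as a scenario variant by raising both rates jointly, but off by default),
directional species turnover such as thermophilization (recruits are drawn
from the same regional pool as the initial community), measurement error in
DBH, and taxonomic drift between censuses.

## Numerical choices and problem sizes

Rarefaction uses log-binomials (`lchoose`) to avoid overflow; the annual
climate summaries exploit the validated 12-months-per-year layout to
summarise by matrix columns; the CV of a constant series is zero only up to
catastrophic cancellation (~1e-6), which tests treat as such. Degenerate
inputs error early and by name: zero-variance t-tests, constant or
collinear predictors (VIF threshold 4 in SEM components, 10 in the
exploratory interaction model), rank-deficient fits, groups too small for
the largest component, incomplete monthly series, tree-cover grids that do
not cover the 50-km disc. Ties in the grouping graph are resolved by
connected components, which are order-invariant.

The validation suite uses problem sizes chosen to keep Monte-Carlo error
well below the tested tolerances while remaining desk-scale: 50 scenario
seeds for SEM sign recovery and estimator accuracy (Monte-Carlo SE ~0.007
on standardized coefficients), 500 seeds for resampling size, exhaustive
enumeration for all abundance partitions with 8 or fewer individuals, and
10^4 random inputs for formula-equivalence checks.

## Limitations

The SEM components are Gaussian OLS; count-type responses with
heteroscedastic errors are only diagnosed (Shapiro, Breusch–Pagan), not
modelled. Correlated errors between endogenous variables are outside the
piecewise framework. The d-separation claims are tested with region
intercepts but without region-interaction terms, matching the constrained
default. Small-plot grouping uses a compatibility heuristic (distance,
region, elevation band); soil or forest-type matching would need additional
metadata.
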