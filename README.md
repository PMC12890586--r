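# forestshift

Tools for quantifying and explaining change in tree **species richness**
across networks of permanent forest inventory plots, aimed at ecologists
working with long-term census data (repeated surveys of all stems with
DBH ≥ 10 cm in fixed plots) across environmental gradients.

## What it computes

For each analysis plot with initial and final censuses `t` years apart:

- **Richness change** `((SP_f − SP_i)/SP_i × 100)/t` (% yr⁻¹, gain-positive),
  where `SP` counts fully identified species; also genus-level and
  rarefaction-based variants (individual-based hypergeometric expectation
  `E[S_n] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n))`), Shannon and inverse-Simpson indices.
- **Stem abundance change** `((n_f − n_0)/n_0 × 100)/t` (% yr⁻¹).
- **Mortality rate** `μ = ((ln n_0 − ln n_s)/t × 100) · t^0.08` (% yr⁻¹),
  the ln-ratio estimator with the standard interval-length correction.
- **Climate covariates** from monthly series (baseline maximum temperature,
  annual precipitation, precipitation seasonality `CV = 100·sd/mean`, and
  their OLS trends over per-plot windows from 1979 to the final census), and
  **landscape integrity** (mean percent tree cover within 50 km).

Inference across unevenly sampled regions uses **balanced bootstrap
t-tests** (30 plots per region per replicate, averaged over 1000
replicates, df = 179) and balanced regression bootstraps. The centrepiece
is a from-scratch **multigroup piecewise structural equation model**: three
component regressions (mortality, stem abundance change, richness change)
along a causal DAG, per-path region-interaction F tests that *constrain*
homogeneous paths to a pooled coefficient and free heterogeneous ones,
directed-separation tests combined by Fisher's `C = −2 Σ ln p` (χ², 2k df),
and decomposition of each predictor's effect on richness change into a
direct effect and three indirect pathways (via stem abundance change, via
mortality, via mortality → stem abundance change), multiplying only
significant standardized links.

A synthetic-data module generates census pairs (log-series communities,
Bernoulli survival, Poisson recruitment, per-individual identification
masking), monthly climate and landscape inputs with a known ground-truth
manifest, so the full pipeline and the SEM estimator are testable without
access-restricted field data.

## Worked example

The packaged demo data (synthetic, three 1-ha Western Amazon plots censused
in 2002 and 2014) run through ingestion, taxonomic standardization, stem
filtering, eligibility selection and per-plot summaries:

```r
library(forestshift)
extdata <- system.file("extdata", package = "forestshift")
census <- read_census_table(file.path(extdata, "demo_census.tsv"),
                            file.path(extdata, "demo_meta.tsv"))
census$stems <- standardize_stems(census$stems,
  read.delim(file.path(extdata, "demo_synonyms.tsv")))
census <- apply_stem_filters(census)
sel <- apply_selection(census)
summ <- summarize_plots(sel$pairs)
summ[, c("plot_id", "sp_initial", "sp_final", "n0", "nf", "ns", "t",
         "richness_change", "stem_abundance_change", "mortality_rate")]
#>   plot_id sp_initial sp_final n0 nf ns  t richness_change stem_abundance_change
#> 1    P001         31       27 71 69 61 12          -1.075               -0.2347
#> 2    P002         24       22 60 59 51 12          -0.694               -0.1389
#> 3    P003         24       25 89 90 78 12           0.347                0.0936
#>   mortality_rate
#> 1           1.54
#> 2           1.65
#> 3           1.34
```

Plot P001 lost 4 of its 31 identified species over 12 years, a decline of
about 1.1% of its initial richness per year; its annual mortality of 1.5%
is typical of old-growth tropical forest. A regional t-test on these three
values finds no directional change:

```r
tt <- regional_ttest(summ$richness_change)
#> mean richness change -0.474 %/yr (t = -1.12, p = 0.38, 95% CI -2.30 to 1.36)
```

At scale, the same chain runs from a single configuration —
`run_pipeline(list(seed = 1))` simulates the default six-region scenario,
builds the analysis table, runs the balanced bootstrap and fits the
multigroup SEM, writing TSV outputs, a DOT path diagram and a checksummed
run manifest (also available from the shell via
`inst/scripts/forestshift --seed 1 --out results/`).

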