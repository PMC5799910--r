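# assemblyscales

Scale-resolved inference of stochastic versus deterministic assembly in
microbial communities.

Soil bacterial composition is shaped both by niche-based selection ("the
environment selects") and by stochastic drift and dispersal. Which one
dominates depends on the spatial scale of comparison: plots a few
kilometres apart share an environment, so their differences are largely
stochastic; plots separated by enough distance to cross a major
environmental boundary (such as the transition between alkaline and
acidic soil regions) differ predictably. `assemblyscales` implements the
statistical machinery to resolve that transition for OTU tables with a
phylogeny and sample metadata:

* **Null-model phylogenetic turnover.** Mean nearest taxon distance
  (MNTD) and its between-sample form betaMNTD, standardized against a
  taxa-shuffle null (tip labels of the patristic matrix permuted,
  default 999 randomizations):
  `ses = (obs − mean_null) / sd_null`, reported as ses.MNTD/NTI per
  sample and betaNTI per pair. Pairs with `|betaNTI| > 2` are classed
  deterministic (`< −2` homogeneous selection, `> 2` variable
  selection), values in `[−2, 2]` stochastic. The null loop is shared
  across pairs and implemented in C++, so hundreds of samples at
  999 randomizations run in seconds.
* **Spatial scales.** Haversine distances (R = 6371 km), equal-width
  distance bins (default 16), a per-scale table of median betaNTI and
  deterministic/stochastic percentages, a Kruskal–Wallis test across
  scales, and PCNM spatial eigenfunctions for use as predictors.
* **Rank-abundance models.** Broken stick, preemption, lognormal, Zipf
  and Zipf–Mandelbrot by Poisson maximum likelihood at ranks, plus the
  neutral zero-sum multinomial via the exact dispersal-limited sampling
  formula (log-space Stirling-number recursion), all compared by
  `AIC = 2·npar − 2·logL`.
* **Variance partitioning.** Adjusted-R² partition of (Hellinger)
  community composition among environmental, latitudinal-trend and PCNM
  spatial blocks, with closed-form inclusion–exclusion fractions that
  sum to one exactly.
* **Diversity statistics.** Bray–Curtis, Chao1, Shannon, Simpson
  evenness, Faith PD, standardized environmental distance, seeded Mantel
  tests, distance-decay regression, alpha-versus-environment
  correlations.
* **A synthetic-community generator** with known assembly processes
  (neutral, homogeneous selection, variable selection, mixed) on a
  1,100 km transect of 27 sites × 9 plots with a mid-transect pH-like
  step — the ground truth against which the whole pipeline is validated.

## Worked example

Simulate a mixed-process community (weak niche filtering plus an
environmental step halfway along the transect), compute betaNTI, and
resolve the process balance by distance:

```r
library(assemblyscales)

sim <- simulate_dataset("mixed", n_taxa = 150, n_sites = 12,
                        plots_per_site = 3, seed = 42)
hz  <- harmonize(sim$table, sim$tree, sim$meta)
D   <- patristic_matrix(hz$tree)

B <- beta_nti(hz$table, D, n_null = 999, seed = 1)
B
#> betaNTI over 36 samples ( 999 randomizations, abundance-weighted )
#>   median betaNTI: 2.576  |betaNTI|>2: 55.7 %

G    <- geodesic_matrix(hz$meta)
bins <- bin_pairs(G, n_bins = 8)
scale_table(B, bins)
#>   scale distance_km n_pairs median_bnti deterministic_pct stochastic_pct   band
#> 1     1       68.75     135        0.39             14.81          85.19  small
#> 2     2      206.25      90        0.64             28.89          71.11  small
#> 3     3      343.75     151        1.65             43.71          56.29 medium
#> 4     4      481.25      65        3.74             78.46          21.54 medium
#> 5     5      618.75      54        5.34             98.15           1.85 medium
#> 6     6      756.25      81        4.96            100.00           0.00 medium
#> 7     7      893.75      27        5.07            100.00           0.00  large
#> 8     8     1031.25      27        4.72            100.00           0.00  large

kruskal_wallis_scales(B, bins)
#> H = 247.5, df = 7, p = 9.5e-50
```

At short distances (first two bins, pairs within the same environmental
regime) the median betaNTI sits inside (−2, 2) and ~85% of pairs classify
stochastic; every bin whose distances force comparisons across the step
has a median above +2 and is dominated by deterministic (variable)
selection — the scale-dependent shift the package is built to detect.

Within a single sample, the rank abundance distribution of the same
simulated community is best described by the neutral zero-sum
multinomial, as expected for dispersal-limited neutral sampling from a
logseries metacommunity:

```r
compare_models(as.numeric(hz$table[1, ]))
#>         model npar logLik   aic delta_aic
#> 1         zsm    2  -66.5 137.0       0.0
#> 2  mandelbrot    3 -140.9 287.7     150.7
#> 3   lognormal    2 -148.2 300.4     163.4
#> 4        zipf    2 -187.2 378.3     241.3
#> 5  preemption    1 -195.9 393.8     256.8
#> 6 brokenstick    0 -267.4 534.9     397.9
```

The full analysis — ingest or simulate, rarefy, diversity statistics,
turnover nulls, scale table, SAD comparison, variance partitioning, with
per-stage TSV/JSON outputs and a hashed MANIFEST — runs from one
configuration object:

```r
cfg <- pipeline_config(
  simulate = list(process = "mixed"),
  rarefy_depth = 500, n_null = 999, n_bins = 16, seed = 7)
run_pipeline(cfg, "results/mixed_run")
```

or from the shell via `inst/scripts/run_pipeline.R --config analysis.yaml`.

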