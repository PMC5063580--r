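# wsbsync

Spatial-synchrony analysis of multi-century insect-outbreak reconstructions
and their climate drivers.

Outbreaks of the western spruce budworm (WSB), the most destructive
defoliator of Douglas-fir and true-fir forests in western North America,
often erupt simultaneously in regions separated by hundreds to thousands of
kilometres. Dendrochronological reconstructions turn this into analyzable
data: one binary record per region, one value per calendar year (outbreak /
no outbreak), spanning centuries. `wsbsync` provides the statistical
pipeline for asking, from such records plus gridded drought-index (PDSI)
reconstructions: how often do outbreaks occur synchronously, is the
synchrony stronger than chance, does it decay with distance, and does
spatially correlated climate (the Moran effect) explain it?

The core methods:

* **Synchronous-period detection** — maximal runs of years in which at
  least `min_regions` (default 3) regions are simultaneously in outbreak for
  at least `min_run` (default 2) years; inclusive durations and
  strictly-internal quiescent gaps.
* **One-dimensional multivariate Ripley's K** — for events (outbreak years,
  episode initiations, cessations) across regions,
  `K(t) = n/(n_a n_b) · Σ_{u∈a} #{v∈b : |u−v| ≤ t}` pooled over ordered
  region pairs, presented as `L(t) = (K(t) − (2t+1))/2` so independence has
  expectation 0. Significance comes from circular-shift surrogates: each
  region's record is rotated by a random offset with wraparound, preserving
  its multi-decadal structure while destroying cross-region alignment.
* **Similarity and Mantel analyses** — outbreak-history similarity
  `(a+b)/(a+b+c+d)` (fraction of years two regions agree), climate
  similarity `−(1/n)·Σ_t |x_t − y_t|`, centroid distances, distance-decay
  OLS, and Mantel / partial Mantel permutation tests (10,000 permutations,
  identity included in the count).
* **Superposed epoch analysis** — drought-anomaly composites over an
  11-year window around synchronous-outbreak initiations/cessations, with
  order-statistic confidence bands from 1,000 Monte-Carlo event draws, plus
  Welch-t contrasts (synchronous vs other years; five pre-initiation years
  vs other years).
* **A synthetic-data generator** — spatially autocorrelated Gaussian
  climate with exponential distance decay and an optional
  northwest/southwest anticorrelated dipole, driving per-region renewal
  processes whose initiations can be forced by drought-then-release years,
  calibrated to the published per-region outbreak statistics.

## Worked example

The package ships the published 13-period synchronous-outbreak table for the
1700–1990 common period of seven compiled regional reconstructions:

```r
library(wsbsync)
summarize_episodes(wsb_synchronous_periods())
#> $n_episodes
#> [1] 13
#> $mean_duration
#> [1] 15.46154
#> $mean_quiescent
#> [1] 7.333333
```

13 synchronous periods averaging 15.5 years, separated by quiescent gaps
averaging 7.3 years — synchrony is the norm, not the exception, across three
centuries.

A full synthetic analysis under strong, strongly-shared climate forcing
(the Moran-effect regime):

```r
sim <- simulate_scenario(transect_scenario(beta = 6, dipole = 0,
                                           lambda_km = 1e4), seed = 42)
periods <- period_table(detect_synchronous_periods(records = sim$outbreaks,
                                                   period = sim$period))
nrow(periods)
#> [1] 21

circular_envelope(sim$outbreaks, "initiations", sim$period,
                  n_sim = 1000, seed = 1)
#> circular-shift K/L envelope (initiations, 1000 sims, alpha = 0.05)
#> significant windows: 0, 1, 13, 14
```

Outbreak initiations cluster across regions within 0–1 years — same-year
L(0) = 0.96 against an envelope topping out at 0.55 — exactly the
fingerprint of a common climate trigger. The epoch analysis shows why:

```r
anom <- compute_anomalies(build_index(sim$climate, names(sim$climate),
                                      "all", sim$period), sim$period)
sea(anom, periods$start, sim$period, n_boot = 1000, seed = 3)$table[4:6, ]
#>   lag composite ci_low ci_high significant
#> 4  -2    -1.200 -0.717   0.737        TRUE
#> 5  -1    -0.884 -0.755   0.678        TRUE
#> 6   0     1.415 -0.658   0.708        TRUE
```

Synchronous outbreaks begin in wet years (+1.4 anomaly at lag 0) preceded by
dry years (−1.2, −0.9 at lags −2, −1): drought-then-release. The Welch
contrasts agree — index PDSI is higher inside synchronous periods
(t = 2.73, p = 0.007) and lower in the five years before initiations
(t = −2.87, p = 0.005).

Real data enter through three CSVs (`year,<region>,...` binary and climate
matrices; `region_id,east_km,north_km` geometry); `run_pipeline(run_config(...))`
sequences everything and writes the period table, K/L envelopes for three
event types, similarity/distance matrices, Mantel results, six SEA
composites and the Welch contrasts, plus a machine-readable
`summary.json`. A thin CLI wrapper with `simulate` / `detect` / `ripley` /
`similarity` / `sea` / `run-all` subcommands lives at `inst/cli/wsbsync.R`.

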