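---
title: "Methods: spatial synchrony of multi-century outbreak reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial synchrony of multi-century outbreak reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsbsync)
```

# The problem

Populations of the western spruce budworm (WSB), a defoliator of Douglas-fir
and true firs, erupt in multi-year outbreaks that often occur simultaneously
in forests separated by hundreds to thousands of kilometres. Because
observational records cover at most a few outbreak cycles,
dendrochronological reconstructions — annual binary records of outbreak and
non-outbreak years, recovered from host/non-host tree-ring comparisons — are
the only way to study this synchrony over centuries. `wsbsync` implements a
complete analysis chain for such data:

1. convert stand-level percent-of-trees records into regional binary records
   (`regionalize()`, `pool_sites()`);
2. detect *synchronous periods*, spans in which at least `min_regions`
   regions are simultaneously in outbreak for at least `min_run` years
   (`detect_synchronous_periods()`);
3. test whether discrete outbreak events (outbreak years, episode
   initiations, episode cessations) co-occur across regions more than
   expected by chance, using a one-dimensional multivariate Ripley's
   K-function with circular-shift randomization envelopes
   (`multivariate_k()`, `circular_envelope()`);
4. quantify distance decay of outbreak-history similarity and climate
   similarity, and their association, with OLS and Mantel / partial Mantel
   permutation tests (`outbreak_similarity()`, `climate_similarity()`,
   `mantel_test()`, `partial_mantel_test()`);
5. composite drought anomalies around synchronous-outbreak initiations and
   cessations with superposed epoch analysis and Monte-Carlo confidence
   intervals, plus Welch-t group contrasts (`sea()`, `group_comparisons()`);
6. generate synthetic multi-region data with tunable Moran-effect forcing so
   that every stage has a self-contained test surface
   (`transect_scenario()`, `simulate_scenario()`).

The central empirical anchor shipped with the package is the published table
of 13 synchronous outbreak periods over the 1700–1990 common period of seven
compiled regional reconstructions (`wsb_synchronous_periods()`), together
with per-region episode summaries (`wsb_region_summaries()`). The regional
binary records themselves are not redistributable, so those reference tables
are both the in-package worked example and the calibration source for the
synthetic generator.

# Conventions for episodes and synchronous periods

All year intervals are closed and durations inclusive: an episode covering
1702–1703 has duration 2. Quiescent gaps are counted strictly *between*
consecutive episodes (`gap = next start − previous end − 1`), never before
the first or after the last; this reproduces the published inter-regional
summary exactly (13 periods totalling 201 years, mean duration
201/13 ≈ 15.46; 12 internal gaps totalling 88 years, mean 7.33).

```{r}
summarize_episodes(wsb_synchronous_periods())
```

Synchronous-period detection takes `min_regions = 3` of 7 and `min_run = 2`
years as defaults. Merging of runs separated by short sub-threshold spells is
available (`max_bridge`) but off by default: the published definition
mentions no merging, yet the published period-years total (201) differs
slightly from the published count of years with three or more regions in
outbreak (199), suggesting about two bridged years in the original analysis.
Because the discrepancy cannot be resolved from the printed record, both the
strict and the bridged behaviour are exposed and the strict one is the
default. Periods touching the study-period boundary are flagged `truncated`
(the New Mexico record ends in 1990 mid-outbreak).

Regionalization follows the "at least 40% of trees for at least two years"
rule: the threshold is a weak inequality applied to exact input fractions,
pooling across sites is tree-weighted (total outbreak trees over total
sampled trees), and the rule is applied to the pooled regional series. The
assignment of sites to regions is user input, not an algorithm.

# The K-function and its randomization envelope

For two event series the bivariate statistic is

$$\hat K_{ab}(t) = \frac{n}{n_a n_b} \sum_{u \in a} \#\{v \in b : |u - v| \le t\},$$

with symmetric inclusive windows (so $t = 0$ counts same-year
co-occurrence), and the pooled multivariate version sums pair counts over
all ordered region pairs, normalized by $\sum_{i \ne j} n_i n_j$. Under
independence a window of half-width $t$ spans $2t + 1$ years, so
$E[\hat K(t)] \approx 2t + 1$; the L-transform
$L(t) = (\hat K(t) - (2t+1))/2$ therefore has expectation approximately zero,
with positive values indicating synchrony. Any affine transform applied
identically to observed and randomized statistics leaves envelope-based
significance unchanged, so this simple standardization is used throughout.

Two deliberate numerical choices:

* **No analytic edge correction.** Observed and simulated statistics share
  the finite-record bias, and significance is judged only against the
  randomization envelope, so edge effects cancel. (Stand-alone K programs
  offer corrections; they are unnecessary under envelope-relative
  inference.)
* **Order-statistic envelopes.** With `n_sim` simulations the envelope is
  $[x_{(\lfloor \alpha/2\,(n_{sim}+1) \rfloor)},
  x_{(\lceil (1-\alpha/2)(n_{sim}+1) \rceil)}]$ per window. For continuous
  exchangeable statistics the probability of the observed value falling
  strictly outside this band is exactly $\alpha$, whereas interpolated
  quantiles are anticonservative at moderate `n_sim` (about 5.9% at
  `n_sim = 200`, $\alpha = 0.05$).

The null model rotates each region's full binary record by an independent
uniform offset in $\{1, \dots, n-1\}$ with wraparound (offset 0 excluded so
every simulation differs from the observed arrangement), then re-extracts
events. Rotation preserves each region's episode-duration structure — up to
one episode split across the wrap seam — while destroying cross-region
alignment; this retains the multi-decadal temporal patterns that
year-by-year shuffling would destroy. Rotating the binary record and
re-extracting events (rather than rotating event lists) is what makes the
initiation/cessation nulls coherent at the seam.

# Similarity indices and Mantel tests

Outbreak-history similarity is the fraction of common-period years on which
two regions agree, $(a+b)/(a+b+c+d)$ with $a$ joint outbreak years and $b$
joint non-outbreak years. Although the source literature labels this index
"Jaccard", the printed formula includes joint absences in the numerator and
is therefore the simple matching coefficient; the formula, not the label, is
implemented. Climate similarity is
$-\tfrac1n \sum_t \sqrt{(x_t - y_t)^2}$, i.e. minus the mean absolute annual
difference of the two drought-index (PDSI) series: 0 for identical series
and increasingly negative for divergent ones.

The Mantel statistic is the Pearson correlation of the upper triangles; the
null distribution comes from simultaneous row/column relabelings of the
second matrix, with the identity permutation included in the count, so
$p \in [1/(n_{perm}+1), 1]$. The default test is two-tailed on $|r|$ (the
source analyses report signed $r$ with $p$ but not tailedness); a one-tailed
option is available for directional hypotheses. The partial Mantel test
residualizes both matrices on the conditioning matrix by OLS over the upper
triangle and permutes the residualized first matrix. If the second matrix is
numerically identical to the conditioning matrix its residuals vanish; the
implementation detects near-zero residual variance and reports $r = 0$ with
a warning rather than correlating numerical noise.

Geographic distances are plane Euclidean distances between region centroids
in km (the rank order of centroid and edge distances is the same for the
study layout, so centroids suffice).

# Superposed epoch analysis

Events are the start (or end) years of synchronous periods. The composite at
lag $l \in \{-5, \dots, +5\}$ is the mean anomaly at `event + l`, where
anomalies subtract the full common-period mean of the chosen climate index
(no detrending, matching the "long-term average" baseline of the source
analyses). Three indices are supported: the all-region mean, a "northwest"
mean (five northern regions) and a "southwest" mean (Colorado and New
Mexico). Confidence bands come from `n_boot` Monte-Carlo draws of
`length(events)` years sampled uniformly *without* replacement within each
draw — the resampling scheme is not stated in the source, and
without-replacement draws mimic the constraint that event years are
distinct. Events whose lag window crosses the period boundary contribute
their in-period lags only; `drop_boundary_events = TRUE` switches to
dropping them. For cessation analyses only lags $\le 0$ are
interpretable (later climate cannot cause an earlier collapse), and the
group contrasts (synchronous vs other years; five pre-start years vs other
years) use Welch's unequal-variance t-test. Pre-start years falling inside
another synchronous period are kept by default (`exclude_in_period` switches
this), since the source is silent on the point.

# The synthetic-data generator

`gen_climate()` draws each year independently (optionally AR(1)) from a
zero-mean multivariate normal with correlation $\exp(-d_{ij}/\lambda)$. A
"dipole" multiplies northwest–southwest cross-group correlations by
$1 - 2\,\delta$: $\delta = 0$ leaves them, $\delta = 0.5$ zeroes them,
$\delta = 1$ negates them. The adjusted matrix is the Schur product of the
exponential-decay correlation with a two-block PSD pattern and is therefore
always positive semi-definite; a defensive eigenvalue check remains.

`gen_outbreaks()` runs each region as a two-state renewal process given its
climate. In quiescence the per-year initiation probability is
$\min\!\big(1, p_0\, e^{\beta T_t} / z\big)$ where $T_t$ indicates a
*drought-then-release* year (mean climate of the prior $k = 3$ years below
zero and the current year at or above zero — the pattern the source analyses
recover two to four years before synchronous initiations),
$p_0 = 1/\text{mean quiescent}$, and $z = \tfrac34 + \tfrac14 e^{\beta}$
renormalizes for the analytic trigger frequency of $1/4$ under white
zero-mean climate. The renormalization is important: it makes $\beta$
*redistribute* initiations onto trigger years without changing the
unconditional initiation rate, so the realized episode durations and
quiescent gaps stay at their configured means for any forcing strength.
Episode lengths are shifted-geometric ($1 + \mathrm{Geom}$, memoryless,
minimum 1), one quiescent year is enforced after each episode so episodes
remain maximal runs with exact calibration, and each region starts at its
stationary renewal state — a non-stationary start would be shared across
regions and inflate the circular-shift false-positive rate. The fraction of
initiations landing on trigger years is $1/(1 + 3e^{-\beta})$: 25% at
$\beta = 0$ (no forcing), ≈87% at $\beta = 3$, ≈99% at $\beta = 6$.

`transect_scenario()` is the calibrated preset emulating the study
conditions: seven regions on a 2,000-km north–south transect (five
northwestern, two southwestern), 291 years from 1700, per-region mean
durations and quiescent periods taken from the published regional summaries,
climate sd 1.8 (the published regional PDSI spreads are ≈1.6–2.2),
correlation e-folding length $\lambda = 1000$ km (climate similarity then
declines steadily over the 0–2,000 km span, as in the gridded
reconstruction), dipole 0.6, and $\beta = 6$ as the strong-forcing default —
the forcing-dominant regime in which essentially all initiations are
climate-triggered. $\beta = 0$ gives mutually independent regions and is
the null for calibration tests.

What the generator does *not* emulate: temporal autocorrelation of PDSI
(white by default; an AR(1) option exists but no analysis result depends on
it), reconstruction lag between defoliation and ring-width response,
observation error in outbreak identification, and any mechanistic WSB
biology (dispersal, parasitoids, phenology). Passing tests on synthetic data
therefore demonstrate the statistical machinery's calibration and power
under the stated generative assumptions, not claims about real WSB
dynamics.

# Test problem sizes and verified properties

The test suite verifies, among others:

* exact agreement of the fast K estimators with brute-force pair enumeration
  on 100 random instances (≤5 series, ≤20 events, n ≤ 300);
* a per-window false-positive rate of 5% ± 2 points for the circular-shift
  envelope on 200 independent-region replicates (7 regions, 291 years,
  `n_sim = 200`), and detection of same-year initiation clustering in ≥90%
  of 50 strong-forcing shared-climate replicates;
* Monte-Carlo Mantel p-values against exhaustive enumeration of all 24
  relabelings of 4-region instances, and the Mantel statistic against
  `vegan::mantel`;
* the SEA contract (zero composites on constant climate, seed-level
  reproducibility, and recovery of the drought-then-release anomaly pattern
  in ≥90% of 100 strong-forcing replicates);
* exact reproduction of the published 13-period table, its mean duration
  (15.46) and mean quiescent period (7.33), from re-encoded binary input.

One documented limitation: with only seven regions (21 pairs) a partial
Mantel test needs $|r| \gtrsim 0.37$ to reach $p < 0.05$, while the
outbreak–climate partial correlation the generator can produce tops out
around 0.16–0.27 even at $\beta \to \infty$ (independent episode durations
decouple outbreak-status agreement from climate agreement). The
outbreak-similarity–climate-similarity association on the study-shaped
scenario is therefore positive on average but individually significant only
in a minority of 291-year replicates — a power constraint inherent to
7-region Mantel designs, worth remembering when interpreting marginal
published p-values near 0.04.
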