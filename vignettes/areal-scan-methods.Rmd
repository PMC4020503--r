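---
title: "Methods: spatial and space-time scan statistics for areal registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial and space-time scan statistics for areal registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealscan)
```

## The problem

A population-based cancer registry reports, for each areal unit (county),
case counts stratified by age group, sex and race, alongside census
population denominators with the same stratification. The question the
scan statistic answers is: *is there a set of contiguous units whose
incidence is higher than the rest of the map can explain*, after the
demographic composition of each unit has been accounted for — and is
that excess larger than chance would produce somewhere on the map?

`arealscan` implements the full analysis chain: indirect standardization
of stratified counts, the Poisson spatial scan over circular and
flexibly shaped windows, space-time Poisson and space-time permutation
scans, Monte Carlo and Gumbel significance, and a synthetic registry
generator that makes the whole pipeline testable without any
restricted-use registry extract.

## Model

Under the null hypothesis the count of unit $i$ is
$Y_i \sim \mathrm{Poisson}(E_i)$, where $E_i$ is the unit's expected
count under indirect standardization:

$$E_i = \sum_s P_{i,s}\, \frac{C_s}{P_s},$$

with $P_{i,s}$ the unit's population in stratum $s$ and $C_s/P_s$ the
study-wide stratum rate over the adjustment axes. By construction
$\sum_i E_i = N$, the observed total, so inference is conditional on
$N$. When the data carry periods, stratum rates are computed per
(stratum × period); purely temporal trends are then absorbed into
$E_i(t)$, mirroring the temporal adjustment of the standard software for
this analysis (SaTScan).

For a candidate window $Z$ with observed count $n$ and expectation $E$,
the log likelihood ratio of the one-sided Poisson scan is

$$\Lambda(Z) \;=\; n \log\frac{n}{E} \;+\; (N-n)\log\frac{N-n}{N-E},
\qquad \text{if } n > E,\ \text{else } 0,$$

with the convention $0\log 0 = 0$. The scan statistic is
$\max_Z \Lambda(Z)$ over the candidate family; the maximising window is
the most likely cluster. Secondary clusters are reported greedily in
decreasing $\Lambda$, skipping any window that shares a region with a
higher-ranked reported cluster (the strict no-overlap rule — consistent
with reports in this field that show exactly one secondary cluster per
analysis). The relative risk reported per window is the inside/outside
rate ratio $(n/E)\,/\,((N-n)/(N-E))$.

### Candidate families

* **Circular** (`circular_windows()`): for every center region, the
  nested sequence of its $k$ nearest neighbours (distance ties broken by
  region id), truncated when the window would exceed a fraction
  (default 0.5, the conventional maximum) of the population at risk; a
  center whose own population exceeds the cap still contributes its
  singleton, so metropolitan units remain scannable. Windows are
  deduplicated by member set.
* **Flexible** (`enumerate_flex_windows()`): all adjacency-connected
  subsets of each anchor's K-nearest-neighbour pool that contain the
  anchor, deduplicated globally. Enumeration is exponential in K; the
  default is K = 10 (the published default of the reference
  implementation of this scan is 15, which is the warning threshold
  here). The flexible scan shares the scoring and Monte Carlo machinery
  with the circular scan, so their p-values are comparable under equal
  seeds. No population-fraction cap is applied to flexible windows: K
  itself bounds the window, as in the reference implementation.
* **Cylinders** (`cylinders()`): every spatial window crossed with every
  contiguous period interval up to half the study span (configurable),
  for the space-time scans.

### Significance

Monte Carlo: R replicate data sets (default 999) are drawn from the
conditional null — the fixed total $N$ redistributed
multinomially with probabilities $E_i/N$ — and each replicate is fully
rescanned; the p-value of a reported cluster is
$(1 + \#\{\text{replicate maxima} \ge \Lambda\})/(R+1)$, with floor
$1/(R+1)$ (0.001 at R = 999). Because every cluster is referred to the
distribution of the *maximum*, the multiplicity of the window family is
controlled without further correction.

Gumbel: the replicate maxima are also well approximated by a Gumbel
law; `gumbel_pvalue()` fits it by the method of moments
($\beta = s\sqrt{6}/\pi$, $\mu = m - \gamma\beta$) and reports the
fitted tail probability. This resolves p-values below the Monte Carlo
floor and smooths the rank granularity; the suite checks agreement with
the Monte Carlo p within 0.02 on $[0.01, 0.5]$.

### Space-time permutation scan

The permutation scan detects space-time *interaction* only. Its
expected count for a cylinder $A$ is the product-of-marginals sum
$\mu_A = \sum_{(z,t)\in A} n_z n_t / N$; purely spatial clusters and
purely temporal trends are absorbed by the marginals. The null permutes
the period labels of individual cases with both marginals held fixed.
Replicate tables are drawn directly from that fixed-margins
distribution with `stats::r2dtable` (Patefield's algorithm), which is
exactly the permutation distribution of case period labels — the
case-level shuffle and the table-level draw are the same law, and the
table-level draw is orders of magnitude faster.

The joint report (`spacetime_analysis()`) encodes a diagnosis rule used
in registry studies: a space-time Poisson cluster that the permutation
scan does not confirm is flagged `trend_artifact` — the apparent local
surge is an artifact of a statewide trend, not a genuine interaction.
For this flag to be informative, the Poisson space-time scan in
`spacetime_scan()` deliberately uses *temporally unadjusted* expected
counts (standardization collapsed over periods and spread uniformly),
so trends remain visible to it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_population_fraction` | 0.5 | circular-window cap, share of population at risk |
| `replicates` | 999 | Monte Carlo/permutation replicates; p floor $1/(R+1)$ |
| `alpha` | 0.05 | significance threshold for reporting/flagging |
| `max_time_fraction` | 0.5 | cylinder length cap, share of the study span |
| `K` | 10 | flexible-scan neighbourhood size (warning above 15) |
| `excluded_regions` | none | units removed before analysis (e.g. one whose cases are institutional rather than residential) |

Distances are Euclidean for planar (projected) coordinates and
great-circle (spherical law of cosines, mean Earth radius 6371.0 km)
for lat/long; the mode is always declared, never inferred — centroid
scale precision does not warrant an ellipsoidal model.

## The synthetic registry: what it emulates

The generator (`synthetic_spec()`, `simulate_registry()`) states a
world once and the validation suite lives in it:

* 67 regions with uniform-random centroids in the unit square and
  Delaunay adjacency;
* a statewide population at risk of exactly 5,358,013 (the adolescent
  and young adult population scale of the emulated statewide registry),
  log-normal across regions (sdlog 1.3 — chosen so the three largest
  regions hold close to a third of the state, the concentration the
  emulated registry reports for its metropolitan primary cluster);
* 5 age groups × 2 sexes × 3 races per region via a symmetric
  Dirichlet(50), with stratum rates following a fixed multiplicative
  profile (female:male 3:1, rising with age, mild race differences) so
  covariate adjustment is genuinely exercised — an adjusted scan must
  *not* flag a merely demographically skewed region, and a test asserts
  exactly that;
* baseline incidence 7.3 per 100,000 person-years over 9 annual
  periods (≈ 3,520 null cases statewide);
* two embedded clusters: relative risk 1.26 over a three-region
  high-population zone pinned to 1,695,088 people, and 1.71 over a
  compact two-region zone pinned to 100,000, at least 0.5 map units
  from the first.

Three design choices deserve explanation:

1. **Cluster relative risks are stated on the observed scale.** A
   registry study reports the observed inside/outside rate ratio, but a
   zone's excess inflates the statewide stratum rates that indirect
   standardization uses, so the observed ratio is systematically below
   the raw Poisson multiplier (by ~8% here, driven by the large
   cluster). `sample_cases()` therefore solves the injection multipliers
   from the stated observed targets by a fixed-point iteration
   (`rr_scale = "observed"`, the default; the solved multipliers for
   the default world are ≈1.29 and ≈1.87). With `rr_scale = "injected"`
   the stated values are used directly as multipliers.
2. **Zone populations are assigned, not hoped for.** The emulated world
   has its largest units adjacent (a metropolitan agglomeration); a
   random draw only sometimes produces that. After cluster geometry is
   resolved, whole regions swap their drawn populations so the primary
   zone holds the largest totals and the secondary zone totals near
   50,000 — a permutation, leaving the population's generative law
   unchanged — and the zones are then rescaled to their stated totals.
3. **Determinism.** The chain is seeded (map: `seed`, population:
   `seed + 1`, cases: `seed + 2`); identical seeds give identical
   registries, and no step uses hidden global randomness.

What the generator does **not** emulate: true county geography and
adjacency, migration, diagnostic-intensity differences, within-period
seasonality, or population change over the study span (denominators are
period-constant). A green test therefore establishes that the
*statistics* behave as specified on data with the stated structure — it
says nothing about any particular real-world cluster's location.

## Numerical choices

* Conditioning check: `sum(E) = N` within 1e-6 relative; violations are
  an error, not a warning, because an unconditioned scan silently
  changes the null.
* `0 log 0 = 0` conventions in the likelihood; windows with `n = N`
  report infinite relative risk as a sentinel (`Inf`), not an error.
* Delaunay adjacency is computed by the brute-force empty-circumcircle
  test (no triangulation library is assumed); points within tolerance
  of a circumcircle do not invalidate a triangle, so co-circular
  configurations keep all tied triangles — deterministic, and on the
  canonical co-circular example (the unit square) it yields both
  diagonals.
* Distance ties in window construction and KNN pools are broken by
  lexicographic region id; ranking ties by (smaller window, then
  lexicographic center), making every reported list reproducible.
* The Gumbel fit requires ≥ 10 replicates with positive variance;
  degenerate replicate sets are an error directing the user to the
  Monte Carlo p-value.
* Monte Carlo scoring is batched: one multinomial draw for all R
  replicates and a single sparse matrix product per scan, which is what
  keeps 999 replicates over ~2,000 windows interactive (~1 s at the
  default world's scale).

## Known limitations

* The flexible-scan enumeration is exact but exponential in K; K > 15
  is possible but warned against.
* The space-time permutation scan requires integer counts (case-level
  permutation has no meaning for fractional tables).
* Centroid-based circular windows approximate polygon-based ones;
  without true boundaries, adjacency for the flexible scan comes from
  Delaunay triangulation or KNN of centroids, which can differ from
  polygon contiguity. This is the main caveat when comparing flexible
  and circular cluster memberships on real maps.
* The one printed secondary-cluster annual rate of the emulated study
  (12.4 per 100,000) does not recompute exactly from its printed
  inputs (65 cases / 58,637 people / 9 years give 12.3); the
  discrepancy is in the source's rounding conventions and is not
  forced.
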