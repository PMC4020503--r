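# arealscan

Spatial and space-time scan statistics for areal disease-registry data.

## Who this is for

Epidemiologists and biostatisticians who have county-level (areal) case
counts stratified by demographics — the shape of data a statewide cancer
registry exports — and want to know whether any set of contiguous units
shows a statistically unusual excess of disease after adjusting for age,
sex and race, and whether any such excess is localised in time.

## What it computes

The core is the one-sided Poisson scan statistic. For a candidate window
`Z` (a set of contiguous units, optionally crossed with a period
interval) with `n` observed and `E` expected cases out of a study total
`N`, the window score is the log likelihood ratio

    LLR(Z) = n log(n/E) + (N - n) log((N - n)/(N - E)),   if n > E, else 0

where `E` comes from indirect standardization: `E_i = sum_s P_is (C_s /
P_s)` with study-wide stratum rates applied to local stratum
populations, so `sum(E) = N` and the scan is conditional on the total.
The most likely cluster maximises `LLR` over the window family;
significance is by conditional Monte Carlo (the fixed total redistributed
as a multinomial with probabilities `E/N`, the maximum re-scanned in
each of R = 999 replicates, p = (1 + exceedances)/(R + 1)), optionally
smoothed by a method-of-moments Gumbel fit to the replicate maxima.
Relative risk is the inside/outside rate ratio
`(n/E) / ((N - n)/(N - E))`.

Window families: circular (nested nearest-neighbour sets up to half the
population at risk), flexibly shaped (adjacency-connected subsets inside
K-nearest-neighbour pools), and cylinders (window × contiguous period
interval) for the space-time Poisson scan. The space-time permutation
scan scores cylinders against product-of-marginals expectations and
permutes case period labels (fixed-margins null), detecting space-time
interaction net of purely spatial clusters and purely temporal trends; a
joint report flags Poisson space-time clusters the permutation scan does
not confirm as statewide-trend artifacts.

A seeded synthetic registry generator (67 regions, stratified
populations, baseline 7.3 cases per 100,000 person-years over 9 annual
periods, embedded clusters at stated observed relative risks) exercises
every stage of the pipeline; the package's validation suite runs
entirely on it.

## Worked example

```r
library(arealscan)

reg <- simulate_registry(synthetic_spec(seed = 7))
cfg <- scan_config(replicates = 999, seed = 11, gumbel = TRUE)
res <- spatial_scan(reg$cases, reg$population, reg$map, cfg)
print(res)
summarize_scan(res, reg$cases, reg$population, cfg)
```

```
<cluster_results> circular scan, N = 4008, R = 999
  #1 [R17,R28,R44] n=1501 E=1265.71 RR=1.30 LLR=31.02 p=<0.001 p_gumbel=3.84e-12
  #2 [R24,R45] n=119 E=75.10 RR=1.60 LLR=11.12 p=<0.001 p_gumbel=0.0005327
  #3 [R06] n=35 E=25.15 RR=1.40 LLR=1.73 p=0.983 p_gumbel=0.9754
  ...

== spatial scan (study span 9 years, R = 999) ==
     column population cases annual/100k   RR   LLR      p
 study area  5,358,013 4,008         8.3
  cluster 1  1,695,088 1,501         9.8 1.30 31.02 <0.001
  cluster 2    100,000   119        13.2 1.60 11.12 <0.001
```

The generator embedded exactly these two clusters (`reg$truth`): an
observed relative risk 1.26 over the three-region metropolitan zone
{R28, R44, R17} and 1.71 over the small two-region zone {R24, R45}. The
scan recovers both: the rank-1 window is exactly the metropolitan zone
(p at the Monte Carlo floor, printed `<0.001`), the rank-2 window the
small zone, and nothing else on the map reaches significance. Realized
RRs (1.30, 1.60 here) scatter around the injected targets seed by seed.
Rates in the table are average annual cases per 100,000 person-years;
`LLR` is the window's log likelihood ratio; `p` is the Monte Carlo
p-value against the replicate-maximum distribution.

The flexible and space-time analyses use the same inputs:

```r
flex <- spatial_scan(reg$cases, reg$population, reg$map, cfg, method = "flexible")
st   <- spacetime_scan(reg$cases, reg$population, reg$map, cfg)
st$trend_artifact   # TRUE when a space-time 'cluster' is just a statewide trend
export_geojson(res, reg$map, "clusters.geojson")
```

A command-line interface covers the same pipeline
(`simulate`, `scan`, `scan-flex`, `scan-st`, `scan-stp`); see
`?cli_main`.

## Layout

- `R/` — geography and file dialects (`geo.R`), stratified counts and
  standardization (`strata.R`), likelihood and windows (`llr.R`,
  `windows.R`), the scan engine and inference (`scan.R`), space-time
  scans (`spacetime.R`), flexible scan (`flexscan.R`), synthetic
  registry (`synth.R`), pipeline/reporting/CLI (`pipeline.R`,
  `report.R`, `cli.R`).
- `tests/testthat/` — unit, property and acceptance tests; independent
  brute-force oracles live in `helper-oracles.R`.
- `vignettes/areal-scan-methods.Rmd` — the model, its assumptions, the
  synthetic world, and the numerical choices.
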