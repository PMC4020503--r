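test_that("the generator chain is deterministic and maps are sound", {
  r1 <- simulate_registry(synthetic_spec(seed = 42))
  r2 <- simulate_registry(synthetic_spec(seed = 42))
  expect_identical(r1$map$regions, r2$map$regions)
  expect_identical(r1$population$count, r2$population$count)
  expect_identical(r1$cases$count, r2$cases$count)
  expect_identical(r1$truth, r2$truth)

  r3 <- simulate_registry(synthetic_spec(seed = 43))
  expect_false(identical(r1$map$regions$x, r3$map$regions$x))

  expect_equal(n_regions(r1$map), 67)
  expect_equal(max(arealscan:::graph_components(r1$map)), 1)  # connected
})

test_that("populations: exact statewide total, stratum sums, pinned zones", {
  reg <- simulate_registry(synthetic_spec(seed = 5))
  expect_equal(sum(reg$population$count), 5358013)
  # stratum counts sum exactly to region totals (largest-remainder rounding)
  tot <- arealscan:::region_totals(reg$population)
  expect_true(all(tot == round(tot)))
  # pinned zone populations: stated primary and secondary totals
  expect_equal(sum(tot[reg$truth[[1]]$regions]), 1695088)
  expect_equal(sum(tot[reg$truth[[2]]$regions]), 100000)
  # zones disjoint and contiguous in the generated adjacency
  al <- adjacency_list(reg$map)
  zs <- lapply(reg$truth, `[[`, "regions")
  expect_equal(length(intersect(zs[[1]], zs[[2]])), 0)
  for (z in zs) expect_true(oracle_connected(z, al))
})

test_that("dirichlet concentration controls stratum-share spread", {
  spec_hi <- synthetic_spec(n_regions = 10, dirichlet_conc = 1e7,
                            clusters = list(), seed = 3)
  reg <- simulate_registry(spec_hi)
  shares <- tapply(reg$population$count, reg$population$region, function(x) x / sum(x))
  for (sh in shares) expect_lt(max(abs(sh - 1 / length(sh))), 0.01)
})

test_that("null statewide incidence calibrates to the stated baseline", {
  # RR == 1 everywhere, flat trend: the empirical rate across seeds should
  # match 7.3 per 100k person-years within Poisson error (scaled-down: 12
  # seeds; expected cases per seed ~3520, so SE of the mean rate ~0.036)
  rates <- vapply(1:12, function(s) {
    reg <- simulate_registry(synthetic_spec(clusters = list(), seed = 500 + s))
    annual_rate_per_100k(sum(reg$cases$count), sum(reg$population$count), 9)
  }, 0)
  se <- 7.3 / sqrt(3520 * 12)
  expect_lt(abs(mean(rates) - 7.3), 4 * se)
})

test_that("expected case totals scale linearly with population", {
  s1 <- synthetic_spec(n_regions = 20, pop_total = 2e6, clusters = list(), seed = 9)
  s2 <- synthetic_spec(n_regions = 20, pop_total = 4e6, clusters = list(), seed = 9)
  n1 <- sum(simulate_registry(s1)$cases$count)
  n2 <- sum(simulate_registry(s2)$cases$count)
  # expected totals 1314 and 2628; ratio 2 within Poisson noise
  expect_equal(n2 / n1, 2, tolerance = 0.12)
})

test_that("ground truth: empty key, constructive contiguity, membership", {
  spec0 <- synthetic_spec(clusters = list(), seed = 2)
  reg0 <- simulate_registry(spec0)
  expect_equal(length(reg0$truth), 0)

  spec3 <- synthetic_spec(
    clusters = list(list(size = 3L, rr = 1.5, anchor = "max_pop",
                         grow = "nearest")), seed = 2)
  reg3 <- simulate_registry(spec3)
  expect_equal(length(reg3$truth[[1]]$regions), 3)
  expect_true(all(reg3$truth[[1]]$regions %in% region_ids(reg3$map)))
  expect_true(oracle_connected(reg3$truth[[1]]$regions,
                               adjacency_list(reg3$map)))
  expect_error(ground_truth(synthetic_spec()), "unresolved")
})

test_that("observed relative risks reproduce the stated cluster targets", {
  # rr is stated on the observed scale; the solved injection multipliers
  # exceed the targets and the realized inside/outside ratios match them
  reg <- simulate_registry(synthetic_spec(seed = 77))
  m <- vapply(reg$truth, `[[`, 0, "rr_inject")
  expect_gt(m[1], 1.26); expect_gt(m[2], 1.71)
  rr_obs <- vapply(1:10, function(s) {
    reg <- simulate_registry(synthetic_spec(seed = 600 + s))
    cas <- arealscan:::region_totals(reg$cases)
    E <- indirect_standardize(reg$cases, reg$population)
    Ereg <- arealscan:::expected_by_region(E, names(cas))
    z <- reg$truth[[1]]$regions
    relative_risk(sum(cas[z]), sum(Ereg[z]), sum(cas))
  }, 0)
  expect_equal(mean(rr_obs), 1.26, tolerance = 0.03)
})

test_that("an embedded strong cluster is recovered with high power and overlap", {
  # observed RR 2.0 over the high-population zone (>= 200 expected cases):
  # detection in every scaled-down replicate, mean Jaccard >= 0.6
  hits <- 0; jac <- numeric(10)
  for (s in 1:10) {
    spec <- synthetic_spec(
      clusters = list(list(size = 3L, rr = 2.0, anchor = "max_pop",
                           grow = "nearest", assign_pop = "top",
                           zone_pop = 1695088)),
      seed = 700 + s)
    reg <- simulate_registry(spec)
    res <- spatial_scan(reg$cases, reg$population, reg$map,
                        scan_config(replicates = 999, seed = 800 + s))
    truth <- reg$truth[[1]]$regions
    hits <- hits + (nrow(res) > 0 && res$p_mc[1] <= 0.05)
    jac[s] <- if (nrow(res)) jaccard(res$members[[1]], truth) else 0
  }
  expect_gte(hits / 10, 0.9)
  expect_gte(mean(jac), 0.6)
})

test_that("covariate adjustment absorbs purely demographic skew", {
  # a region whose population is demographically tilted toward high-rate
  # strata (young women here have the highest rates) must NOT be flagged
  # by the adjusted scan even though its crude rate is elevated
  spec <- synthetic_spec(n_regions = 20, pop_total = 3e6, clusters = list(),
                         seed = 31)
  reg <- simulate_registry(spec)
  pop <- reg$population
  # tilt region R01: move most men into the female strata (same totals)
  r1 <- pop$region == "R01"
  f <- r1 & pop$sex == "F"; m <- r1 & pop$sex == "M"
  shift <- floor(pop$count[m] * 0.8)
  pop$count[m] <- pop$count[m] - shift
  pop$count[f] <- pop$count[f] + shift
  spec2 <- arealscan:::solve_injection(
    resolve_clusters(spec, reg$map, pop), pop)
  cases <- sample_cases(pop, spec2)
  res_adj <- spatial_scan(cases, pop, reg$map,
                          scan_config(replicates = 199, seed = 32))
  flagged <- nrow(res_adj) > 0 &&
    any(vapply(which(res_adj$p_mc <= 0.05),
               function(i) "R01" %in% res_adj$members[[i]], TRUE))
  expect_false(flagged)

  # the unadjusted scan (no covariates) does see the demographic excess
  res_crude <- spatial_scan(cases, pop, reg$map,
                            scan_config(replicates = 199, seed = 33),
                            adjust_axes = character())
  crude_flags <- nrow(res_crude) > 0 &&
    any(vapply(which(res_crude$p_mc <= 0.05),
               function(i) "R01" %in% res_crude$members[[i]], TRUE))
  expect_true(crude_flags)
})
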