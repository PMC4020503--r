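test_that("poisson_llr matches the closed form and its conventions", {
  # registry worked example (rounded published inputs)
  expect_equal(poisson_llr(1300, 1118, 3526), 21.1278, tolerance = 1e-4)
  expect_equal(poisson_llr(65, 38, 3526), 7.99684, tolerance = 1e-4)
  # indicator: no excess, no score
  expect_equal(poisson_llr(50, 50, 100), 0)
  expect_equal(poisson_llr(10, 40, 100), 0)
  # all cases inside: second term vanishes by the 0 log 0 convention
  expect_equal(poisson_llr(100, 60, 100), 100 * log(100 / 60))
  # strictly increasing in n beyond E
  lls <- poisson_llr(31:60, 30, 100)
  expect_true(all(diff(lls) > 0))
  # agreement with the plain-loop oracle on a grid
  for (n in c(0, 3, 17, 40)) {
    expect_equal(poisson_llr(n, 12.5, 40), oracle_llr(n, 12.5, 40))
  }
  expect_error(poisson_llr(11, 5, 10), "n must")
  expect_error(poisson_llr(3, 0, 10), "E must")
})

test_that("relative_risk matches Table-style arithmetic and sentinels", {
  expect_equal(round(relative_risk(1300, 1118, 3526), 2), 1.26)
  expect_equal(relative_risk(65, 38, 3526), 1.72387, tolerance = 1e-4)
  expect_equal(relative_risk(25, 25, 100), 1)
  expect_identical(relative_risk(100, 60, 100), Inf)   # sentinel, not error
  expect_equal(relative_risk(0, 5, 100), 0)
})

test_that("whole-study-area window scores llr 0 and rr 1", {
  expect_equal(poisson_llr(200, 200, 200), 0)
  expect_equal(relative_risk(150, 150, 200), 1)
})

test_that("circular windows: caps, ties, dedup, brute-force match", {
  # 3 equidistant regions, equal weights, cap 0.34: only singletons
  tri <- region_map(c("A", "B", "C"), c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  w <- circular_windows(tri, c(A = 1, B = 1, C = 1), 0.34)
  expect_equal(n_windows(w), 3)
  expect_true(all(lengths(w$members) == 1))

  # 5-region line, equal weights, cap 0.5: sizes 1 and 2, deduplicated;
  # distance ties broken lexicographically
  lm5 <- line_map(5)
  w5 <- circular_windows(lm5, stats::setNames(rep(1, 5), LETTERS[1:5]), 0.5)
  keys <- sort(vapply(window_members(w5), paste, "", collapse = ","))
  expect_equal(keys, sort(c("A", "B", "C", "D", "E",
                            "A,B", "B,C", "C,D", "D,E")))

  # a region holding 60% of the weight keeps its singleton window
  wts <- c(A = 60, B = 10, C = 10, D = 10, E = 10)
  wbig <- circular_windows(lm5, wts, 0.5)
  expect_true("A" %in% vapply(window_members(wbig), paste, "", collapse = ","))

  # nestedness: members are exactly the radius_rank nearest to the center
  mm <- random_planar_map(12, seed = 5)
  D <- region_distances(mm)
  ww <- circular_windows(mm, stats::setNames(runif(12, 1, 2), region_ids(mm)), 0.5)
  for (j in seq_len(n_windows(ww))) {
    ctr <- ww$center[j]
    k <- length(ww$members[[j]])
    nearest <- region_ids(mm)[order(D[ctr, ], region_ids(mm))][1:k]
    expect_setequal(window_members(ww)[[j]], nearest)
  }

  expect_error(circular_windows(lm5, wts, 0.6), "max_fraction")
  expect_error(circular_windows(lm5, wts, 0), "max_fraction")
})

test_that("scan: null data, hot spot, overlap rule, conditioning check", {
  ids <- sprintf("R%02d", 1:10)
  m <- random_planar_map(10, seed = 7)
  E <- stats::setNames(rep(5, 10), ids)
  w <- circular_windows(m, stats::setNames(rep(1, 10), ids), 0.5)

  # counts equal to expectations: nothing reported
  res0 <- scan(E, ec(E, ids), w, scan_config(replicates = 19, seed = 1))
  expect_equal(nrow(res0), 0)

  # single hot region dominates; matches the exhaustive oracle
  obs <- E; obs[3] <- 20; obs[1] <- 2; obs[8] <- 3
  N <- sum(obs)
  Ec <- E * N / sum(E)
  res <- scan(obs, ec(Ec, ids), w, scan_config(replicates = 99, seed = 2))
  orc <- oracle_circular_best(m$regions[c("x", "y")], ids,
                              rep(1, 10), obs, Ec, N)
  expect_equal(sort(res$members[[1]]), sort(orc$members))
  expect_equal(res$llr[1], orc$llr, tolerance = 1e-9)

  # reported clusters are pairwise disjoint
  set.seed(3)
  obs2 <- null_counts(E, ids, 80)
  res2 <- scan(obs2, ec(E * 80 / 50, ids), w, scan_config(replicates = 19, seed = 3))
  if (nrow(res2) > 1) {
    all_mem <- unlist(res2$members)
    expect_equal(anyDuplicated(all_mem), 0)
  }

  # unconditioned expectations are rejected
  expect_error(scan(obs, ec(E, ids), w, scan_config(replicates = 9)),
               "not conditioned")
})

test_that("monte_carlo_null: determinism, degenerate totals, exact trinomial", {
  ids <- c("A", "B")
  m <- region_map(ids, c(0, 1), c(0, 0))
  w <- circular_windows(m, c(A = 1, B = 1), 0.5)   # singletons only
  e <- ec(c(1, 1), ids, N = 2)

  d1 <- monte_carlo_null(e, w, R = 50, seed = 9)
  d2 <- monte_carlo_null(e, w, R = 50, seed = 9)
  expect_identical(as.numeric(d1), as.numeric(d2))

  # N = 0: all replicate maxima zero
  d0 <- monte_carlo_null(ec(c(0, 0), ids, N = 0), w, R = 10, seed = 1)
  expect_equal(as.numeric(d0), rep(0, 10))

  # exact enumeration: counts (2,0), (1,1), (0,2) give max llr in {2 ln 2, 0},
  # with P(max = 0) = P(1,1) = 1/2
  d <- monte_carlo_null(e, w, R = 2000, seed = 4)
  expect_true(all(abs(d) < 1e-12 | abs(d - 2 * log(2)) < 1e-12))
  expect_gt(mean(d == 0), 0.45)
  expect_lt(mean(d == 0), 0.55)
})

test_that("mc_pvalue follows the (1 + exceedances)/(R + 1) rank rule", {
  d <- structure(as.numeric(1:999), R = 999L, class = "replicate_dist")
  expect_equal(mc_pvalue(1000, d), 0.001)   # exceeds every replicate
  expect_equal(mc_pvalue(0, d), 1)          # every replicate max >= 0 >= obs
  expect_equal(mc_pvalue(500.5, d), 0.5)    # exactly 499 maxima above
  expect_equal(mc_pvalue(1, d), 1)
})

test_that("gumbel_pvalue: location identity, monotonicity, recovery", {
  set.seed(99)
  d <- structure(rnorm(999, 10, 2), R = 999L, class = "replicate_dist")
  m <- mean(d); s <- sd(d)
  beta <- s * sqrt(6) / pi
  mu <- m - 0.5772156649015329 * beta
  expect_equal(gumbel_pvalue(mu, d), 1 - exp(-1), tolerance = 1e-12)
  ps <- gumbel_pvalue(seq(5, 25, by = 0.5), d)
  expect_true(all(diff(ps) < 0))

  # parameter recovery from genuine Gumbel(mu = 2, beta = 0.5) draws
  set.seed(12)
  u <- runif(10000)
  g <- structure(2 - 0.5 * log(-log(u)), R = 10000L, class = "replicate_dist")
  beta_hat <- sd(g) * sqrt(6) / pi
  mu_hat <- mean(g) - 0.5772156649015329 * beta_hat
  expect_lt(abs(beta_hat - 0.5), 0.02)
  expect_lt(abs(mu_hat - 2), 0.02)

  dz <- structure(rep(3, 100), R = 100L, class = "replicate_dist")
  expect_error(gumbel_pvalue(1, dz), "variance")
  expect_error(gumbel_pvalue(1, structure(1:5, R = 5L, class = "replicate_dist")),
               "10 replicates")
})

test_that("rank-1 window equals exhaustive maximisation on small maps", {
  for (s in 1:4) {
    set.seed(s)
    n <- sample(4:8, 1)
    ids <- sprintf("R%02d", 1:n)
    m <- random_planar_map(n, seed = 100 + s)
    wts <- stats::setNames(runif(n, 0.5, 2), ids)
    E0 <- stats::setNames(runif(n, 2, 12), ids)
    N <- 150
    obs <- null_counts(E0, ids, N)
    obs[sample(n, 1)] <- obs[sample(n, 1)] + 15      # force an excess
    N <- sum(obs)
    Ec <- E0 * N / sum(E0)
    w <- circular_windows(m, wts, 0.5)
    res <- scan(obs, ec(Ec, ids), w, scan_config(replicates = 9, seed = s))
    orc <- oracle_circular_best(m$regions[c("x", "y")], ids, wts, obs, Ec, N)
    expect_equal(sort(res$members[[1]]), sort(orc$members))
    expect_equal(res$llr[1], orc$llr, tolerance = 1e-9)
  }
})
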