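#' Synthetic registry specification
#'
#' The stated world of the validation suite: a 67-region map with
#' (age x sex x race)-stratified populations around 80,000 adolescents
#' and young adults per region (statewide ~5.4 million), a baseline
#' incidence of 7.3 cases per 100,000 person-years, 9 annual periods, and
#' two embedded contiguous clusters — relative risk 1.26 over a
#' three-region high-population zone and 1.71 over a two-region
#' low-population zone — mirroring the scale of a statewide AYA thyroid
#' cancer registry. Stratum baseline rates follow a fixed multiplicative
#' profile (female:male 3:1, rising with age, mild race differences) so
#' covariate adjustment is genuinely exercised.
#'
#' @param n_regions number of regions (>= 3).
#' @param axes named list of stratum levels.
#' @param baseline_rate population-weighted mean incidence, cases per
#'   100,000 person-years.
#' @param periods study periods (calendar years).
#' @param pop_scale mean region population (log-normal).
#' @param pop_total statewide population at risk the region draws are
#'   normalised to (default 5,358,013, the emulated statewide AYA
#'   population); `NULL` leaves the raw log-normal draws.
#' @param pop_sdlog log-normal dispersion of region populations; the
#'   default 1.3 reproduces the population concentration of a realistic
#'   67-county state, whose three largest counties hold close to a third
#'   of the statewide population at risk.
#' @param dirichlet_conc symmetric Dirichlet concentration of stratum
#'   shares within a region (larger = more homogeneous).
#' @param rate_profile named list of per-axis multiplicative rate factors
#'   (recycled to the axis levels); the overall scale is normalised to
#'   `baseline_rate` against the generated population.
#' @param clusters list of cluster specs: each a list with `rr` (> 0) and
#'   either `regions` (explicit ids) or `size` plus `anchor` (`"max_pop"`,
#'   `"pop_near:<value>"`, or a region id), optional `grow` rule (see
#'   [resolve_clusters()]), `periods` (subset of study periods) and
#'   `min_separation` (centroid distance to previously placed clusters).
#' @param rr_scale `"observed"` (default): cluster `rr` values are target
#'   observed inside/outside relative risks, and the Poisson injection
#'   multipliers are solved from them (see [sample_cases()]);
#'   `"injected"`: `rr` values are used directly as Poisson multipliers.
#' @param trend multiplicative per-period statewide factor (scalar 1 or a
#'   vector over periods).
#' @param seed integer seed; the whole generator chain is deterministic
#'   given it (map uses `seed`, population `seed + 1`, cases `seed + 2`).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions = 67L,
                           axes = list(age = c("15-19", "20-24", "25-29", "30-34", "35-39"),
                                       sex = c("F", "M"),
                                       race = c("white", "black", "other")),
                           baseline_rate = 7.3,
                           periods = 2000:2008,
                           pop_scale = 80000,
                           pop_total = 5358013,
                           pop_sdlog = 1.3,
                           dirichlet_conc = 50,
                           rate_profile = list(age = c(0.3, 0.6, 1.0, 1.5, 2.1),
                                               sex = c(1.5, 0.5),
                                               race = c(1.05, 0.85, 1.0)),
                           clusters = default_clusters(),
                           rr_scale = c("observed", "injected"),
                           trend = 1,
                           seed = 1L) {
  rr_scale <- match.arg(rr_scale)
  if (n_regions < 3) stop("n_regions must be >= 3")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  for (cl in clusters)
    if (!is.null(cl$rr) && cl$rr <= 0) stop("cluster relative risks must be > 0")
  trend <- rep_len(trend, length(periods))
  structure(list(n_regions = as.integer(n_regions), axes = axes,
                 baseline_rate = baseline_rate, periods = periods,
                 pop_scale = pop_scale, pop_total = pop_total,
                 pop_sdlog = pop_sdlog,
                 dirichlet_conc = dirichlet_conc, rate_profile = rate_profile,
                 clusters = clusters, rr_scale = rr_scale, trend = trend,
                 seed = as.integer(seed), resolved = NULL),
            class = "synthetic_spec")
}

#' Default embedded clusters of the synthetic registry
#'
#' A high-population three-region zone at relative risk 1.26 (a large
#' metropolitan cluster: the zone holds the three largest region
#' populations, pinned to the stated cluster population of 1,695,088 —
#' 31.6% of the statewide 5,358,013) and a compact two-region zone
#' pinned to 100,000 at relative risk 1.71, at least 0.5 map units away
#' (a small remote cluster of two ~50,000-person regions).
#'
#' @return list of cluster specs for [synthetic_spec()].
#' @export
default_clusters <- function() {
  list(list(size = 3L, rr = 1.26, anchor = "max_pop", grow = "nearest",
            assign_pop = "top", zone_pop = 1695088),
       list(size = 2L, rr = 1.71, anchor = "pop_near:50000",
            grow = "nearest", assign_pop = "near:50000", zone_pop = 100000,
            min_separation = 0.5))
}

#' Generate a synthetic region map
#'
#' Uniform random centroids in the unit square with Delaunay adjacency;
#' fully reproducible given the spec seed.
#'
#' @param spec a `synthetic_spec`.
#' @return a `region_map` with adjacency.
#' @export
make_map <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_regions
  ids <- sprintf("R%02d", seq_len(n))
  m <- region_map(ids, stats::runif(n), stats::runif(n), mode = "planar")
  build_adjacency(m, "delaunay")
}

# integerise `total * shares` so the parts sum exactly to `total`
largest_remainder <- function(total, shares) {
  total <- as.numeric(total); shares <- as.numeric(shares)
  raw <- total * shares / sum(shares)
  fl <- floor(raw)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    ord <- order(raw - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Generate stratified region populations
#'
#' Region totals are log-normal around `pop_scale`, normalised (when the
#' spec states `pop_total`) so the statewide population at risk is exact;
#' within-region stratum shares are symmetric-Dirichlet; integerisation
#' uses largest-remainder rounding so stratum counts sum exactly to the
#' region total. The population is period-constant (`NA` period).
#'
#' @param map a `region_map`.
#' @param spec a `synthetic_spec`.
#' @return a `stratified_counts` of kind `"population"`.
#' @export
make_population <- function(map, spec) {
  set.seed(spec$seed + 1L)
  ids <- region_ids(map)
  draws <- stats::rlnorm(length(ids),
                         log(spec$pop_scale) - spec$pop_sdlog^2 / 2,
                         spec$pop_sdlog)
  totals <- if (is.null(spec$pop_total)) round(draws)
            else largest_remainder(spec$pop_total, draws)
  strata <- expand.grid(spec$axes, stringsAsFactors = FALSE)
  S <- nrow(strata)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- stats::rgamma(S, shape = spec$dirichlet_conc)
    cnt <- largest_remainder(totals[i], g / sum(g))
    rows[[i]] <- cbind(data.frame(region = ids[i], period = NA_integer_,
                                  stringsAsFactors = FALSE),
                       strata, count = cnt)
  }
  stratified_counts(do.call(rbind, rows), names(spec$axes), "population")
}

# per-stratum annual rates (per person-year), normalised so the
# population-weighted mean is baseline_rate per 100,000
stratum_rates <- function(population, spec) {
  strata <- expand.grid(spec$axes, stringsAsFactors = FALSE)
  prof <- rep(1, nrow(strata))
  for (a in names(spec$axes)) {
    f <- rep_len(spec$rate_profile[[a]], length(spec$axes[[a]]))
    prof <- prof * f[match(strata[[a]], spec$axes[[a]])]
  }
  key <- do.call(paste, c(strata, sep = "\r"))
  pkey <- do.call(paste, c(population[names(spec$axes)], sep = "\r"))
  P_s <- tapply(population$count, pkey, sum)[key]
  P_s[is.na(P_s)] <- 0
  scale <- (spec$baseline_rate / 1e5) / stats::weighted.mean(prof, P_s)
  stats::setNames(prof * scale, key)
}

#' Resolve cluster specs against a generated map and population
#'
#' Materialises `size`/`anchor` cluster specs into explicit contiguous
#' region sets: the anchor is chosen by the stated rule, then the zone is
#' grown one adjacent region at a time by the `grow` rule — `"nearest"`
#' (default: nearest centroid to the anchor, keeping the zone compact the
#' way real metropolitan clusters are), `"max_pop"`, or
#' `"pop_near:<value>"`. Explicit `regions` specs are validated for
#' contiguity.
#'
#' @param spec a `synthetic_spec`.
#' @param map,population generated by [make_map()]/[make_population()].
#' @return the spec with `resolved` filled in.
#' @export
resolve_clusters <- function(spec, map, population) {
  ids <- region_ids(map)
  pop <- region_totals(population, ids)
  al <- adjacency_list(map)
  D <- region_distances(map)
  taken <- character(0)
  resolved <- list()
  for (cl in spec$clusters) {
    if (!is.null(cl$regions)) {
      regs <- as.character(cl$regions)
      if (!all(regs %in% ids)) stop("cluster references unknown region(s)")
      if (!connected_in(regs, al)) stop("explicit cluster regions are not contiguous")
    } else {
      cand <- setdiff(ids, taken)
      if (!is.null(cl$min_separation) && length(taken))
        cand <- cand[apply(D[cand, taken, drop = FALSE], 1, min) >= cl$min_separation]
      if (!length(cand)) stop("no admissible anchor for cluster spec")
      anchor <- if (identical(cl$anchor, "max_pop")) {
        cand[order(-pop[cand], cand)][1]
      } else if (grepl("^pop_near:", cl$anchor %||% "")) {
        target <- as.numeric(sub("^pop_near:", "", cl$anchor))
        cand[order(abs(pop[cand] - target), cand)][1]
      } else if (!is.null(cl$anchor) && cl$anchor %in% ids) {
        cl$anchor
      } else stop("unknown cluster anchor rule: ", format(cl$anchor))
      grow <- cl$grow %||% "nearest"
      regs <- anchor
      while (length(regs) < (cl$size %||% 1L)) {
        nb <- setdiff(unique(unlist(al[regs])), c(regs, taken))
        if (!length(nb)) break
        pick <- if (identical(grow, "max_pop")) {
          nb[order(-pop[nb], nb)][1]
        } else if (grepl("^pop_near:", grow)) {
          target <- as.numeric(sub("^pop_near:", "", grow))
          nb[order(abs(pop[nb] - target), nb)][1]
        } else {                      # "nearest": keep the zone compact
          nb[order(D[nb, anchor], nb)][1]
        }
        regs <- c(regs, pick)
      }
    }
    if (any(regs %in% taken)) stop("cluster region sets must be disjoint")
    taken <- c(taken, regs)
    resolved[[length(resolved) + 1L]] <-
      list(regions = regs, rr = cl$rr,
           periods = cl$periods %||% spec$periods,
           assign_pop = cl$assign_pop, zone_pop = cl$zone_pop)
  }
  spec$resolved <- resolved
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

connected_in <- function(regs, al) {
  if (length(regs) <= 1) return(TRUE)
  seen <- regs[1]; queue <- regs[1]
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- intersect(al[[v]], regs)
    new <- setdiff(nb, seen)
    seen <- c(seen, new); queue <- c(queue, new)
  }
  length(seen) == length(regs)
}

#' Sample stratified case counts
#'
#' Counts for (region i, stratum s, period t) are drawn
#' `Poisson(P_{i,s} * r_s * trend_t * RR_i(t))`, with `r_s` the stratum
#' baseline annual rate (normalised to the spec's population-weighted
#' baseline), `trend_t` the statewide per-period factor and `RR_i(t)` the
#' product of the risk multipliers of clusters covering region i in
#' period t (1 elsewhere).
#'
#' A cluster spec's `rr` is stated on the scale a registry study reports:
#' the *observed* inside/outside relative risk. Because every cluster's
#' excess inflates the statewide rates that indirect standardization
#' uses, the observed relative risk of a zone is smaller than its raw
#' Poisson multiplier; the generator therefore solves the multipliers
#' `RR_i(t)` from the stated observed targets by a fixed-point iteration
#' (see [resolve_clusters()]), so the emulated registry reproduces the
#' stated relative risks in expectation. Set `rr_scale = "injected"` in
#' the spec to use the stated values directly as Poisson multipliers.
#'
#' @param population a generated `stratified_counts` population.
#' @param spec a resolved `synthetic_spec` (see [resolve_clusters()]; an
#'   unresolved spec with explicit-region clusters only is resolved
#'   against `map`).
#' @param map the `region_map` (needed to resolve clusters if not done).
#' @return a `stratified_counts` of kind `"cases"` with one row per
#'   (region, stratum, period).
#' @export
sample_cases <- function(population, spec, map = NULL) {
  if (is.null(spec$resolved)) {
    if (is.null(map)) stop("spec is unresolved; supply `map` or call resolve_clusters()")
    spec <- resolve_clusters(spec, map, population)
  }
  spec <- solve_injection(spec, population)
  set.seed(spec$seed + 2L)
  axes <- names(spec$axes)
  r_s <- stratum_rates(population, spec)
  pkey <- do.call(paste, c(population[axes], sep = "\r"))
  base_lambda <- population$count * r_s[pkey]     # per person-year rate x pop

  P <- length(spec$periods)
  rr_rp <- matrix(1, nrow(population), P)         # row x period risk multiplier
  for (cl in spec$resolved) {
    rows <- population$region %in% cl$regions
    cols <- spec$periods %in% cl$periods
    rr_rp[rows, cols] <- rr_rp[rows, cols] * cl$rr_inject
  }
  out <- vector("list", P)
  for (t in seq_len(P)) {
    lam <- base_lambda * spec$trend[t] * rr_rp[, t]
    df <- population[c("region", axes)]
    df$period <- spec$periods[t]
    df$count <- stats::rpois(length(lam), lam)
    out[[t]] <- df
  }
  cases <- do.call(rbind, out)
  cases <- stratified_counts(cases, axes, "cases")
  attr(cases, "truth") <- ground_truth(spec)
  cases
}

#' Ground-truth answer key of a resolved spec
#'
#' @param spec a resolved `synthetic_spec`.
#' @return list of injected clusters: `regions`, `rr` (target observed
#'   relative risk), `rr_inject` (solved Poisson multiplier, when
#'   available), `periods`; empty list when the spec embeds none.
#' @export
ground_truth <- function(spec) {
  if (is.null(spec$resolved)) stop("spec is unresolved; call resolve_clusters()")
  spec$resolved
}

#' Generate a complete synthetic registry
#'
#' Chains [make_map()], [make_population()], [resolve_clusters()],
#' [assign_cluster_populations()] and [sample_cases()] deterministically
#' from the spec seed.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `map`, `population`, `cases`, `truth`, `spec` (the
#'   resolved spec).
#' @export
simulate_registry <- function(spec = synthetic_spec()) {
  map <- make_map(spec)
  population <- make_population(map, spec)
  spec <- resolve_clusters(spec, map, population)
  population <- assign_cluster_populations(population, spec)
  spec <- solve_injection(spec, population)
  cases <- sample_cases(population, spec)
  list(map = map, population = population, cases = cases,
       truth = ground_truth(spec), spec = spec)
}

#' Relabel population draws so cluster zones hold their stated populations
#'
#' The emulated world fixes the population structure of the embedded
#' zones (a metropolitan primary cluster holding the largest region
#' populations, a small secondary zone of ~50,000-person regions). A
#' random draw only sometimes produces that structure, so after cluster
#' geometry is resolved the drawn region populations are permuted — whole
#' regions swap their stratified population — until each zone with an
#' `assign_pop` rule holds the required totals: `"top"` gives the zone
#' the largest totals (anchor first), `"near:<value>"` the totals closest
#' to the target. A permutation leaves the population's generative law
#' unchanged; regions in other clusters are never raided. Zones whose
#' spec states an exact population (`zone_pop`, e.g. the printed
#' primary-cluster population 1,695,088) are then rescaled to that total,
#' with the remaining regions rescaled so the statewide total is
#' preserved.
#'
#' @param population a generated `stratified_counts` population.
#' @param spec a resolved `synthetic_spec`.
#' @return the relabeled population.
#' @export
assign_cluster_populations <- function(population, spec) {
  if (is.null(spec$resolved)) stop("spec is unresolved; call resolve_clusters()")
  cluster_regions <- unlist(lapply(spec$resolved, `[[`, "regions"))
  for (cl in spec$resolved) {
    rule <- cl$assign_pop
    if (is.null(rule)) next
    for (j in seq_along(cl$regions)) {
      a <- cl$regions[j]
      tot <- region_totals(population)
      # donors: any region not in another cluster and not already placed
      pool <- setdiff(names(tot),
                      c(setdiff(cluster_regions, cl$regions),
                        cl$regions[seq_len(j - 1L)]))
      b <- if (identical(rule, "top")) {
        pool[order(-tot[pool], pool)][1]
      } else if (grepl("^near:", rule)) {
        target <- as.numeric(sub("^near:", "", rule))
        pool[order(abs(tot[pool] - target), pool)][1]
      } else stop("unknown assign_pop rule: ", rule)
      if (!identical(a, b)) {
        ra <- population$region == a; rb <- population$region == b
        population$region[ra] <- b; population$region[rb] <- a
      }
    }
  }
  pin_zone_populations(population, spec)
}

# Solve the Poisson injection multipliers m_k from the stated observed
# relative risks: each cluster's excess inflates the average rate outside
# the other clusters, so the observed inside/outside ratio of zone k is
# m_k / (1 + sum_{j != k} (m_j - 1) lambda_j / (Lambda - lambda_k)), with
# lambda the null expected counts. Fixed-point iteration; exact in
# expectation. Under rr_scale = "injected" the multipliers are the stated
# values themselves.
solve_injection <- function(spec, population) {
  done <- all(vapply(spec$resolved, function(cl) !is.null(cl$rr_inject), TRUE))
  if (done || !length(spec$resolved)) return(spec)
  if (identical(spec$rr_scale, "injected")) {
    for (k in seq_along(spec$resolved))
      spec$resolved[[k]]$rr_inject <- spec$resolved[[k]]$rr
    return(spec)
  }
  r_s <- stratum_rates(population, spec)
  pkey <- do.call(paste, c(population[names(spec$axes)], sep = "\r"))
  base <- population$count * r_s[pkey]            # per-row annual null mean
  lam_row_year <- function(regs) sum(base[population$region %in% regs])
  tr <- spec$trend
  # null expected counts per zone over its own period window
  lam <- vapply(spec$resolved, function(cl)
    lam_row_year(cl$regions) * sum(tr[spec$periods %in% cl$periods]), 0)
  Lam <- lam_row_year(unique(population$region)) * sum(tr)
  tgt <- vapply(spec$resolved, `[[`, 0, "rr")
  m <- tgt
  for (it in 1:100) {
    m_new <- vapply(seq_along(m), function(k) {
      infl <- 1 + sum((m[-k] - 1) * lam[-k]) / (Lam - lam[k])
      tgt[k] * infl
    }, 0)
    if (max(abs(m_new - m)) < 1e-12) { m <- m_new; break }
    m <- m_new
  }
  for (k in seq_along(spec$resolved)) spec$resolved[[k]]$rr_inject <- m[k]
  spec
}

# rescale zones with a stated population (`zone_pop`) to that exact total,
# and the remaining regions so the statewide total is preserved
pin_zone_populations <- function(population, spec) {
  pinned <- Filter(function(cl) !is.null(cl$zone_pop), spec$resolved)
  if (!length(pinned)) return(population)
  grand <- sum(population$count)
  zone_regions <- unlist(lapply(pinned, `[[`, "regions"))
  rest <- setdiff(unique(population$region), zone_regions)
  rescale_set <- function(pop, regions, target) {
    cur <- region_totals(pop)[regions]
    new_tot <- largest_remainder(target, cur)
    for (k in seq_along(regions)) {
      rows <- which(pop$region == regions[k])
      pop$count[rows] <- largest_remainder(new_tot[k], pop$count[rows])
    }
    pop
  }
  for (cl in pinned)
    population <- rescale_set(population, cl$regions, cl$zone_pop)
  rest_target <- grand - sum(vapply(pinned, `[[`, 0, "zone_pop"))
  if (rest_target < 0) stop("zone_pop targets exceed the statewide population")
  rescale_set(population, rest, rest_target)
}

#' Jaccard overlap between two region sets
#' @param a,b character vectors of region ids.
#' @return |a n b| / |a u b|.
#' @export
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
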