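#' Space-time cylinders
#'
#' Crosses every spatial window with every contiguous period interval of
#' length at most `max_time_fraction` of the study span (at least one
#' period, so a cap below `1/P` still yields the single-period
#' intervals).
#'
#' @param windows a `scan_windows` spatial family.
#' @param periods sorted vector of study periods (e.g. calendar years).
#' @param max_time_fraction temporal cap in `(0, 1]`; 0.5 is the usual
#'   default for the Poisson space-time scan.
#' @return a `scan_cylinders` object.
#' @export
cylinders <- function(windows, periods, max_time_fraction = 0.5) {
  if (max_time_fraction <= 0 || max_time_fraction > 1)
    stop("max_time_fraction must lie in (0, 1]")
  P <- length(periods)
  if (P < 1) stop("need at least one period")
  lmax <- max(1L, floor(max_time_fraction * P + 1e-9))
  iv <- do.call(rbind, lapply(seq_len(P), function(s) {
    e <- s:min(P, s + lmax - 1L)
    cbind(s, e)
  }))
  structure(list(windows = windows, periods = periods,
                 t_start = rep(iv[, 1], times = n_windows(windows)),
                 t_end = rep(iv[, 2], times = n_windows(windows)),
                 window = rep(seq_len(n_windows(windows)), each = nrow(iv))),
            class = "scan_cylinders")
}

#' @export
print.scan_cylinders <- function(x, ...) {
  cat(sprintf("<scan_cylinders> %d cylinders = %d windows x %d intervals over %d periods\n",
              length(x$window), n_windows(x$windows),
              length(x$window) / n_windows(x$windows),
              length(x$periods)))
  invisible(x)
}

#' Number of cylinders
#' @param cyl a `scan_cylinders`.
#' @return integer.
#' @export
n_cylinders <- function(cyl) length(cyl$window)

# cylinders x (region x period) cells indicator; cells vectorised
# region-fastest: cell(r, p) = r + (p - 1) * n_regions
cylinder_matrix <- function(cyl) {
  nreg <- length(cyl$windows$regions)
  P <- length(cyl$periods)
  mem <- cyl$windows$members
  ii <- jj <- vector("list", n_cylinders(cyl))
  for (c in seq_len(n_cylinders(cyl))) {
    m <- mem[[cyl$window[c]]]
    ps <- cyl$t_start[c]:cyl$t_end[c]
    jj[[c]] <- as.vector(outer(m, (ps - 1L) * nreg, `+`))
    ii[[c]] <- rep.int(c, length(jj[[c]]))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                       dims = c(n_cylinders(cyl), nreg * P))
}

# region x period count matrix from stratified_counts (or pass-through)
as_region_period_matrix <- function(x, regions, periods) {
  if (is.matrix(x)) {
    if (!identical(dim(x), c(length(regions), length(periods))))
      stop("count matrix dimensions do not match regions x periods")
    return(x)
  }
  if (!inherits(x, "stratified_counts")) stop("need a matrix or stratified_counts")
  x <- expand_periods(x, periods)
  m <- matrix(0, length(regions), length(periods),
              dimnames = list(regions, as.character(periods)))
  ri <- match(x$region, regions); pi <- match(x$period, periods)
  ok <- !is.na(ri) & !is.na(pi)
  for (k in which(ok)) m[ri[k], pi[k]] <- m[ri[k], pi[k]] + x$count[k]
  m
}

# expected_counts -> region x period matrix of E
expected_matrix <- function(expected, regions, periods) {
  m <- matrix(0, length(regions), length(periods))
  if (all(is.na(expected$period))) {
    # period-collapsed E spread uniformly over periods (no temporal adjustment)
    E <- expected_by_region(expected, regions)
    m[] <- E / length(periods)
  } else {
    ri <- match(expected$region, regions); pi <- match(expected$period, periods)
    ok <- !is.na(ri) & !is.na(pi)
    m[cbind(ri[ok], pi[ok])] <- expected$E[ok]
  }
  m
}

cylinder_meta <- function(cyl) {
  meta <- data.frame(center = cyl$windows$center[cyl$window],
                     size = lengths(cyl$windows$members)[cyl$window],
                     t_start = cyl$periods[cyl$t_start],
                     t_end = cyl$periods[cyl$t_end],
                     stringsAsFactors = FALSE)
  meta$spatial <- cyl$windows$members[cyl$window]
  meta
}

#' Space-time Poisson scan
#'
#' Identical likelihood-ratio scoring to the purely spatial [scan()], with
#' observed and expected counts aggregated over cylinders (spatial window
#' x contiguous period interval). The Monte Carlo null redistributes the
#' fixed total N over the full region x period grid with probabilities
#' `E/N`. With a single period this reproduces [scan()] exactly. Secondary
#' cylinders follow the spatial no-overlap rule.
#'
#' @param observed region x period count matrix (regions in map order) or
#'   a `stratified_counts`.
#' @param expected `expected_counts` with per-(region, period) rows (from
#'   [indirect_standardize()] with `by_period = TRUE`), or period-collapsed
#'   rows, which are spread uniformly over periods (no temporal
#'   adjustment — a statewide trend then surfaces as a cluster).
#' @param cyl a [cylinders()] family.
#' @param config a [scan_config()].
#' @return a `cluster_results` with `t_start`/`t_end` columns.
#' @export
st_poisson_scan <- function(observed, expected, cyl, config = scan_config()) {
  regions <- cyl$windows$regions
  periods <- cyl$periods
  obs <- as_region_period_matrix(observed, regions, periods)
  Em <- expected_matrix(expected, regions, periods)
  N <- sum(obs)
  check_conditioned(as.vector(Em), N)
  B <- cylinder_matrix(cyl)
  res <- scan_engine(B, as.vector(obs), as.vector(Em), N, cylinder_meta(cyl))
  if (!is.null(config$seed)) set.seed(config$seed)
  dist <- if (N == 0) numeric(config$replicates) else {
    counts <- stats::rmultinom(config$replicates, round(N),
                               as.vector(Em) / sum(Em))
    replicate_maxima(B, counts, as.vector(Em), N)
  }
  finalize_results(res, new_replicate_dist(dist, config$seed), config,
                   regions, N, shape = "space-time")
}

#' Space-time marginals
#'
#' Per-zone and per-period case totals; the building blocks of the
#' space-time permutation scan's expected counts.
#'
#' @param counts region x period count matrix.
#' @return list with `n_z` (per region), `n_t` (per period), `N`.
#' @export
st_marginals <- function(counts) {
  list(n_z = rowSums(counts), n_t = colSums(counts), N = sum(counts))
}

#' Permutation-scan expected count of a cylinder
#'
#' The product-of-marginals expectation `mu_A = sum_{(z,t) in A}
#' n_z * n_t / N`: what the cylinder would contain if case times were
#' independent of case locations. Purely spatial clusters and purely
#' temporal trends are absorbed by the marginals, so only space-time
#' interaction raises `n` above `mu`.
#'
#' @param marginals output of [st_marginals()].
#' @param zone integer/logical index of member regions.
#' @param interval integer indices of member periods.
#' @return expected count `mu`.
#' @export
stp_expected <- function(marginals, zone, interval) {
  if (marginals$N == 0) stop("no cases: N = 0")
  sum(outer(marginals$n_z[zone], marginals$n_t[interval]) / marginals$N)
}

#' Space-time permutation scan
#'
#' Detects space-time interaction clusters net of purely spatial and
#' purely temporal structure. Each cylinder is scored by the Poisson
#' generalized log likelihood ratio with the product-of-marginals
#' expectation [stp_expected()] in place of E. The null holds both
#' marginals fixed and permutes the period labels of individual cases;
#' replicate tables are drawn directly from that fixed-margins
#' distribution (Patefield's algorithm, `stats::r2dtable`).
#'
#' @param observed region x period count matrix (integer counts) or a
#'   `stratified_counts`.
#' @param cyl a [cylinders()] family.
#' @param R permutation replicates.
#' @param seed RNG seed.
#' @param config optional [scan_config()] (alpha/gumbel/replicates; `R`
#'   and `seed` arguments win if given).
#' @return a `cluster_results` with `t_start`/`t_end` columns.
#' @export
stp_scan <- function(observed, cyl, R = 999L, seed = NULL,
                     config = scan_config(replicates = R, seed = seed)) {
  regions <- cyl$windows$regions
  periods <- cyl$periods
  obs <- as_region_period_matrix(observed, regions, periods)
  if (any(obs != round(obs))) stop("permutation scan needs integer counts")
  marg <- st_marginals(obs)
  N <- marg$N
  B <- cylinder_matrix(cyl)
  # the product-of-marginals expectation is a per-cell quantity, so the
  # shared engine aggregates it to mu exactly as it aggregates E
  mu_cells <- as.vector(outer(marg$n_z, marg$n_t) / max(N, 1))
  mu <- pmax(as.numeric(B %*% mu_cells), .Machine$double.xmin)
  res <- scan_engine(B, as.vector(obs), mu_cells, N, cylinder_meta(cyl))

  if (!is.null(seed)) set.seed(seed)
  dist <- if (N == 0) numeric(config$replicates) else {
    tabs <- stats::r2dtable(config$replicates, round(marg$n_z), round(marg$n_t))
    M <- vapply(tabs, as.vector, numeric(length(obs)))
    col_max(.llr(as.matrix(B %*% M), pmax(mu, .Machine$double.xmin), N))
  }
  finalize_results(res, new_replicate_dist(dist, seed), config,
                   regions, N, shape = "space-time permutation")
}

#' Joint space-time analysis with trend-artifact diagnosis
#'
#' Runs the space-time Poisson scan (without temporal adjustment of the
#' expected counts, so statewide trends are visible to it) and the
#' space-time permutation scan on the same data, and flags the common
#' artifact: a significant Poisson space-time cluster that the
#' permutation scan does not confirm indicates a statewide temporal
#' trend, not a genuine local surge.
#'
#' @param observed region x period counts (matrix or `stratified_counts`).
#' @param expected `expected_counts` for the Poisson space-time scan.
#' @param cyl a [cylinders()] family.
#' @param config a [scan_config()].
#' @return list with `st` and `stp` `cluster_results` and logical
#'   `trend_artifact`.
#' @export
spacetime_analysis <- function(observed, expected, cyl,
                               config = scan_config()) {
  st <- st_poisson_scan(observed, expected, cyl, config)
  stp <- stp_scan(observed, cyl, R = config$replicates,
                  seed = config$seed, config = config)
  st_sig <- nrow(st) > 0 && min(st$p_mc) <= config$alpha
  stp_sig <- nrow(stp) > 0 && min(stp$p_mc) <= config$alpha
  list(st = st, stp = stp, trend_artifact = st_sig && !stp_sig)
}
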