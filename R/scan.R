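#' Scan configuration
#'
#' @param max_population_fraction maximum circular-window share of the
#'   population at risk, in `(0, 0.5]`.
#' @param replicates Monte Carlo replicate count R (999 gives a minimum
#'   attainable p-value of 0.001).
#' @param seed RNG seed for the Monte Carlo / permutation null; `NULL`
#'   leaves the RNG state alone.
#' @param alpha significance level used when reports flag clusters.
#' @param max_time_fraction maximum temporal length of a space-time
#'   cylinder as a fraction of the study span, in `(0, 0.5]` (1 allowed
#'   only via [cylinders()] directly).
#' @param K neighbourhood size of the flexibly shaped scan.
#' @param excluded_regions region ids removed before any analysis.
#' @param gumbel also compute Gumbel-approximation p-values.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(max_population_fraction = 0.5,
                        replicates = 999L,
                        seed = NULL,
                        alpha = 0.05,
                        max_time_fraction = 0.5,
                        K = 10L,
                        excluded_regions = character(),
                        gumbel = FALSE) {
  if (max_population_fraction <= 0 || max_population_fraction > 0.5)
    stop("max_population_fraction must lie in (0, 0.5]")
  if (replicates < 1) stop("replicates must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(max_population_fraction = max_population_fraction,
                 replicates = as.integer(replicates),
                 seed = seed, alpha = alpha,
                 max_time_fraction = max_time_fraction,
                 K = as.integer(K),
                 excluded_regions = as.character(excluded_regions),
                 gumbel = isTRUE(gumbel)),
            class = "scan_config")
}

# column maxima of a (possibly Matrix) numeric matrix
col_max <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 1L) return(as.numeric(m[1L, ]))
  m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
}

# Shared scoring/ranking engine.
# B: candidates x cells sparse indicator; obs, E: per-cell vectors; N total.
# meta: data.frame of per-candidate descriptors, must carry a `spatial`
# list-column (region indices, for the no-overlap rule), `center`, `size`.
scan_engine <- function(B, obs, E, N, meta) {
  n_in <- as.numeric(B %*% obs)
  E_in <- as.numeric(B %*% E)
  llr <- .llr(n_in, E_in, N)
  rr <- relative_risk(n_in, pmax(E_in, .Machine$double.xmin), N)
  ord <- order(-llr, meta$size, meta$center)
  keep <- integer(0)
  used <- rep(FALSE, max(unlist(meta$spatial)))
  for (i in ord) {
    if (llr[i] <= 0) break
    sp <- meta$spatial[[i]]
    if (any(used[sp])) next
    used[sp] <- TRUE
    keep <- c(keep, i)
  }
  res <- meta[keep, , drop = FALSE]
  res$n <- n_in[keep]; res$E <- E_in[keep]
  res$llr <- llr[keep]; res$rr <- rr[keep]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

# max-llr over candidates for each column of a cell x R count matrix
replicate_maxima <- function(B, counts, E, N) {
  if (N == 0) return(numeric(ncol(counts)))
  n_mat <- as.matrix(B %*% counts)
  col_max(.llr(n_mat, as.numeric(B %*% E), N))
}

new_replicate_dist <- function(x, seed) {
  structure(as.numeric(x), R = length(x), seed = seed,
            class = "replicate_dist")
}

#' @export
print.replicate_dist <- function(x, ...) {
  cat(sprintf("<replicate_dist> R = %d, max-llr range [%.3f, %.3f]\n",
              attr(x, "R"), min(x), max(x)))
  invisible(x)
}

#' Conditional Monte Carlo null distribution
#'
#' Generates R replicate data sets under the constant-risk null by
#' redistributing the fixed observed total N across regions as a
#' multinomial with probabilities `E_i / N` (the conditional Poisson
#' procedure), rescans every candidate window, and records each
#' replicate's maximum log likelihood ratio.
#'
#' @param expected an `expected_counts` object (purely spatial: rows are
#'   collapsed over periods).
#' @param windows a `scan_windows` object.
#' @param R replicate count.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return a `replicate_dist`: numeric vector of length R of replicate
#'   max-llr values.
#' @export
monte_carlo_null <- function(expected, windows, R = 999L, seed = NULL) {
  E <- expected_by_region(expected, windows$regions)
  N <- expected_total(expected)
  check_conditioned(E, N)
  if (!is.null(seed)) set.seed(seed)
  B <- window_matrix(windows)
  if (N == 0) return(new_replicate_dist(numeric(R), seed))
  counts <- stats::rmultinom(R, round(N), E / sum(E))
  new_replicate_dist(replicate_maxima(B, counts, E, N), seed)
}

check_conditioned <- function(E, N, tol = 1e-6) {
  if (N > 0 && abs(sum(E) - N) > tol * N)
    stop(sprintf("expected counts are not conditioned on the total: sum(E) = %.8g, N = %.8g",
                 sum(E), N))
  invisible(TRUE)
}

#' Monte Carlo rank p-value
#'
#' `p = (1 + #\{replicate maxima >= observed\}) / (R + 1)`; the smallest
#' attainable value is `1/(R+1)` (0.001 at R = 999).
#'
#' @param observed_llr observed statistic (scalar or vector).
#' @param dist a `replicate_dist`.
#' @return p-value(s) on the grid `k/(R+1)`.
#' @export
mc_pvalue <- function(observed_llr, dist) {
  R <- attr(dist, "R")
  vapply(observed_llr,
         function(x) (1 + sum(dist >= x)) / (R + 1),
         numeric(1))
}

#' Gumbel-approximation p-value
#'
#' Fits a Gumbel (type-I extreme value) distribution to the replicate
#' maxima by the method of moments — `beta = s * sqrt(6) / pi`,
#' `mu = m - gamma * beta` with `gamma` the Euler–Mascheroni constant —
#' and returns the fitted upper-tail probability
#' `1 - exp(-exp(-(x - mu)/beta))`, a smoother (and below `1/(R+1)`
#' resolvable) alternative to the Monte Carlo rank.
#'
#' @inheritParams mc_pvalue
#' @return p-value(s) in (0, 1).
#' @export
gumbel_pvalue <- function(observed_llr, dist) {
  if (length(dist) < 10)
    stop("Gumbel approximation needs at least 10 replicates")
  m <- mean(dist); s <- stats::sd(dist)
  if (!is.finite(s) || s <= 0)
    stop("replicate maxima have zero variance; use the Monte Carlo p-value")
  beta <- s * sqrt(6) / pi
  mu <- m - 0.5772156649015329 * beta
  p <- 1 - exp(-exp(-(observed_llr - mu) / beta))
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Purely spatial Poisson scan
#'
#' Scores every candidate window by the Poisson log likelihood ratio on
#' its aggregated observed and expected counts, ranks windows by llr,
#' reports the most likely cluster and non-overlapping secondary clusters
#' (greedy: a window sharing any region with a higher-ranked reported
#' cluster is skipped), and attaches conditional Monte Carlo (and
#' optionally Gumbel) p-values computed against the distribution of the
#' replicate maximum — the correct multiplicity control for a scan.
#'
#' @param observed named per-region case counts.
#' @param expected an `expected_counts` conditioned on the observed total
#'   (`sum(E) = N`, checked at 1e-6 relative tolerance).
#' @param windows a `scan_windows` family ([circular_windows()] or
#'   [enumerate_flex_windows()]).
#' @param config a [scan_config()].
#' @return a `cluster_results` data.frame: one row per reported cluster
#'   with members, n, E, llr, rr, p_mc (and p_gumbel if requested), plus
#'   the replicate distribution as attribute `"replicate_dist"`.
#' @export
scan <- function(observed, expected, windows, config = scan_config()) {
  ids <- windows$regions
  obs <- observed[ids]
  if (anyNA(obs)) stop("observed counts missing for some regions")
  N <- sum(obs)
  E <- expected_by_region(expected, ids)
  check_conditioned(E, N)
  meta <- data.frame(center = windows$center,
                     size = lengths(windows$members),
                     stringsAsFactors = FALSE)
  meta$spatial <- windows$members
  B <- window_matrix(windows)
  res <- scan_engine(B, as.numeric(obs), E, N, meta)
  dist <- monte_carlo_null(expected, windows,
                           R = config$replicates, seed = config$seed)
  finalize_results(res, dist, config, windows$regions, N,
                   shape = windows$shape)
}

finalize_results <- function(res, dist, config, regions, N, shape) {
  res$p_mc <- if (nrow(res)) mc_pvalue(res$llr, dist) else numeric(0)
  if (config$gumbel)
    res$p_gumbel <- if (nrow(res)) gumbel_pvalue(res$llr, dist) else numeric(0)
  res$members <- I(lapply(res$spatial, function(i) regions[i]))
  res$spatial <- NULL
  structure(res,
            N = N, shape = shape, config = config, replicate_dist = dist,
            class = c("cluster_results", "data.frame"))
}

#' @export
print.cluster_results <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cluster_results> %s scan, N = %s, R = %d\n",
              attr(x, "shape"), format(attr(x, "N")),
              cfg$replicates))
  if (!nrow(x)) { cat("  no window in excess (all llr = 0)\n"); return(invisible(x)) }
  show <- utils::head(x, 10L)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  #%d [%s] n=%g E=%.2f RR=%.2f LLR=%.2f p=%s%s\n",
                show$rank[i],
                paste(show$members[[i]], collapse = ","),
                show$n[i], show$E[i], show$rr[i], show$llr[i],
                format_pvalue(show$p_mc[i], cfg$replicates),
                if (!is.null(show$p_gumbel))
                  sprintf(" p_gumbel=%.4g", show$p_gumbel[i]) else ""))
  }
  invisible(x)
}

format_pvalue <- function(p, R) {
  floor_p <- 1 / (R + 1)
  if (p <= floor_p) sprintf("<%.4g", floor_p) else sprintf("%.3f", p)
}
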