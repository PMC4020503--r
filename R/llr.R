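#' Poisson scan log likelihood ratio
#'
#' The scan statistic's window score. For a window with `n` observed and
#' `E` expected cases out of a study total `N`, the log likelihood ratio is
#'
#'   `n * log(n/E) + (N - n) * log((N - n)/(N - E))`
#'
#' when the window is in excess (`n > E`), and 0 otherwise (the one-sided
#' indicator of a high-rate cluster). Terms with a zero count follow the
#' convention `0 * log(0/x) = 0`.
#'
#' Vectorised over `n` and `E` (including matrix `n` with `E` recycled down
#' columns, used by the batched Monte Carlo scorer).
#'
#' @param n observed count(s) inside the window, `0 <= n <= N`.
#' @param E expected count(s) inside the window under the null.
#' @param N total observed cases in the study area.
#' @return log likelihood ratio(s), `>= 0`.
#' @export
poisson_llr <- function(n, E, N) {
  if (any(n < 0) || any(n > N)) stop("n must lie in [0, N]")
  if (any(E <= 0 & n > 0)) stop("E must be positive wherever n > 0")
  .llr(n, E, N)
}

# no-validation kernel shared by the scan engines
.llr <- function(n, E, N) {
  t1 <- n * log(n / E)
  t1[n == 0] <- 0
  t2 <- (N - n) * log((N - n) / (N - E))
  t2[n == N] <- 0
  v <- t1 + t2
  v[n <= E] <- 0
  v
}

#' Relative risk of a window
#'
#' Ratio of the observed/expected rate inside the window to that outside:
#' `(n/E) / ((N - n)/(N - E))`. A window containing every case (`n = N`)
#' has infinite relative risk, returned as `Inf` rather than an error.
#'
#' @inheritParams poisson_llr
#' @return relative risk(s).
#' @export
relative_risk <- function(n, E, N) {
  if (any(n < 0) || any(n > N)) stop("n must lie in [0, N]")
  if (any(E <= 0 & n > 0)) stop("E must be positive wherever n > 0")
  out <- (n / E) / ((N - n) / (N - E))
  out[n == N & E < N] <- Inf
  out[n == 0] <- 0
  out
}
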