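#' Candidate window families
#'
#' A `scan_windows` object is the candidate-cluster family a scan
#' maximises over: a list of region-index sets with bookkeeping (center,
#' size) and a sparse membership matrix builder.
#'
#' @name scan_windows
NULL

new_scan_windows <- function(members, center, regions, shape) {
  structure(list(members = members,        # list of integer index vectors
                 center = center,          # character center/anchor ids
                 regions = regions,        # region ids indexed by members
                 shape = shape),
            class = "scan_windows")
}

#' @export
print.scan_windows <- function(x, ...) {
  cat(sprintf("<scan_windows> %d %s windows over %d regions (sizes %d..%d)\n",
              length(x$members), x$shape, length(x$regions),
              min(lengths(x$members)), max(lengths(x$members))))
  invisible(x)
}

#' Number of candidate windows
#' @param w a `scan_windows`.
#' @return integer.
#' @export
n_windows <- function(w) length(w$members)

#' Member region ids of each window
#' @param w a `scan_windows`.
#' @return list of character vectors.
#' @export
window_members <- function(w) lapply(w$members, function(i) w$regions[i])

#' Circular scan windows
#'
#' For every center region, the nested nearest-neighbour sequence
#' `{center}`, `{center + 1 NN}`, ... truncated when the cumulative
#' population at risk would exceed `max_fraction` of the total. Distance
#' ties are broken by lexicographic region id. A center whose own weight
#' exceeds the cap still contributes its singleton window, so heavily
#' populated units remain scannable. Windows are deduplicated by member
#' set across centers.
#'
#' @param map a `region_map`.
#' @param weights per-region population at risk: named numeric vector or
#'   a `stratified_counts` population table.
#' @param max_fraction maximum window share of the total population at
#'   risk, in `(0, 0.5]`.
#' @return a `scan_windows` object of shape `"circular"`.
#' @export
circular_windows <- function(map, weights, max_fraction = 0.5) {
  if (!is.numeric(max_fraction) || max_fraction <= 0 || max_fraction > 0.5)
    stop("max_fraction must lie in (0, 0.5]")
  ids <- region_ids(map)
  if (inherits(weights, "stratified_counts"))
    weights <- region_totals(weights, ids)
  w <- weights[ids]
  if (anyNA(w)) stop("weights missing for some regions")
  total <- sum(w)
  if (total <= 0) stop("total weight must be positive")
  D <- region_distances(map)
  cap <- max_fraction * total * (1 + 1e-12)

  members <- vector("list", 0L); center <- character(0)
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(ids)) {
    ord <- order(D[i, ], ids)           # self first (distance 0)
    cum <- cumsum(w[ord])
    kmax <- max(1L, max(which(cum <= cap), 0L))
    for (k in seq_len(kmax)) {
      idx <- sort(ord[seq_len(k)])
      key <- paste(idx, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        members[[length(members) + 1L]] <- idx
        center[[length(center) + 1L]] <- ids[i]
      }
    }
  }
  new_scan_windows(members, center, ids, "circular")
}

# sparse windows x regions indicator matrix
window_matrix <- function(w) {
  Matrix::sparseMatrix(
    i = rep(seq_along(w$members), lengths(w$members)),
    j = unlist(w$members),
    x = 1,
    dims = c(length(w$members), length(w$regions)))
}
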