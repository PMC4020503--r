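#' K-nearest-neighbour candidate pool of the flexible scan
#'
#' The anchor region plus its `K - 1` nearest regions by centroid
#' distance; ties broken lexicographically by region id, so repeated
#' calls are identical.
#'
#' @param map a `region_map`.
#' @param anchor region id.
#' @param K neighbourhood size including the anchor, `1 <= K <= n`.
#' @return character vector of K region ids (anchor first).
#' @export
knn_neighborhood <- function(map, anchor, K) {
  ids <- region_ids(map)
  if (!anchor %in% ids) stop("unknown anchor region: ", anchor)
  if (K < 1 || K > length(ids)) stop("K must lie in [1, n_regions]")
  D <- region_distances(map)
  ord <- order(D[anchor, ], ids)
  ids[ord][seq_len(K)]
}

#' Enumerate flexibly shaped windows
#'
#' For every anchor region, all subsets of its K-nearest-neighbour pool
#' that contain the anchor and are connected in the adjacency graph,
#' found by incremental connected-subgraph expansion (each set emitted
#' exactly once per anchor) and globally deduplicated by member set.
#' Enumeration is exponential in K; above K = 15 (the published FleXScan
#' default) the candidate family becomes unwieldy, so a warning is
#' raised.
#'
#' @param map a `region_map` with symmetric adjacency.
#' @param K neighbourhood size (default 10).
#' @return a `scan_windows` of shape `"flexible"`.
#' @export
enumerate_flex_windows <- function(map, K = 10L) {
  if (is.null(map$adjacency))
    stop("map has no adjacency; call build_adjacency() first")
  if (K > 15)
    warning("K > 15: connected-subset enumeration is exponential in K")
  ids <- region_ids(map)
  comp <- graph_components(map)
  if (max(comp) > 1)
    warning("adjacency graph is disconnected; windows stay within components")
  al <- adjacency_list(map)
  adj_idx <- lapply(al, function(nb) match(nb, ids))
  D <- region_distances(map)

  members <- vector("list", 0L); center <- character(0)
  seen <- new.env(parent = emptyenv())
  for (a in seq_along(ids)) {
    pool <- ids[order(D[a, ], ids)][seq_len(min(K, length(ids)))]
    pool_idx <- match(pool, ids)
    allowed <- rep(FALSE, length(ids)); allowed[pool_idx] <- TRUE
    sets <- connected_subsets(a, adj_idx, allowed)
    for (s in sets) {
      idx <- sort(s)
      key <- paste(idx, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        members[[length(members) + 1L]] <- idx
        center[[length(center) + 1L]] <- ids[a]
      }
    }
  }
  new_scan_windows(members, center, ids, "flexible")
}

# all connected vertex sets containing `root` within `allowed`, each once:
# classic grow-with-exclusion recursion over the expansion frontier
connected_subsets <- function(root, adj_idx, allowed) {
  out <- list()
  recurse <- function(set, banned) {
    out[[length(out) + 1L]] <<- set
    ext <- unique(unlist(adj_idx[set], use.names = FALSE))
    ext <- ext[allowed[ext] & !(ext %in% set) & !(ext %in% banned)]
    if (!length(ext)) return()
    ext <- sort(ext)
    for (v in ext) {
      recurse(c(set, v), banned)
      banned <- c(banned, v)
    }
  }
  recurse(root, integer(0))
  out
}

#' Flexibly shaped spatial scan
#'
#' The purely spatial Poisson scan over adjacency-connected irregular
#' windows: [enumerate_flex_windows()] supplies the candidate family and
#' the scoring, Monte Carlo, p-value and secondary-cluster machinery is
#' shared with [scan()], so circular and flexible p-values are comparable
#' under identical seeds. With `K = 1` the family degenerates to the
#' singleton windows.
#'
#' @inheritParams scan
#' @param map a `region_map` with adjacency.
#' @param K neighbourhood size.
#' @return a `cluster_results`.
#' @export
flexible_scan <- function(observed, expected, map, K = 10L,
                          config = scan_config()) {
  windows <- enumerate_flex_windows(map, K)
  scan(observed, expected, windows, config)
}
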