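# Independent oracles: deliberately plain, loop-based re-implementations
# used to cross-check the package's vectorised code paths on tiny inputs.
# They share no code with the package internals.

oracle_llr <- function(n, E, N) {
  if (n <= E) return(0)
  t1 <- if (n == 0) 0 else n * log(n / E)
  t2 <- if (N - n == 0) 0 else (N - n) * log((N - n) / (N - E))
  t1 + t2
}

# exhaustive circular scan: every (center, rank) prefix window
oracle_circular_best <- function(xy, ids, weights, obs, E, N, max_fraction = 0.5) {
  D <- as.matrix(stats::dist(xy))
  total <- sum(weights)
  best <- NULL; best_llr <- -Inf
  for (i in seq_along(ids)) {
    ord <- order(D[i, ], ids)
    for (k in seq_along(ids)) {
      mem <- ord[1:k]
      if (k > 1 && sum(weights[mem]) > max_fraction * total * (1 + 1e-12)) break
      llr <- oracle_llr(sum(obs[mem]), sum(E[mem]), N)
      if (llr > best_llr + 1e-9) { best <- sort(mem); best_llr <- llr }
    }
  }
  list(members = ids[best], llr = best_llr)
}

oracle_connected <- function(mem, adj) {
  if (length(mem) <= 1) return(TRUE)
  seen <- mem[1]; queue <- mem[1]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    new <- setdiff(intersect(adj[[v]], mem), seen)
    seen <- c(seen, new); queue <- c(queue, new)
  }
  length(seen) == length(mem)
}

# exhaustive flexible scan: bitmask over each anchor's K-neighbourhood,
# subsets filtered by an independent BFS connectivity check
oracle_flex_best <- function(xy, ids, adj, K, obs, E, N) {
  D <- as.matrix(stats::dist(xy))
  best <- NULL; best_llr <- -Inf
  for (a in seq_along(ids)) {
    pool <- ids[order(D[a, ], ids)][seq_len(K)]
    rest <- setdiff(pool, ids[a])
    for (mask in 0:(2^length(rest) - 1)) {
      inc <- if (length(rest)) rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0] else character(0)
      mem <- c(ids[a], inc)
      if (!oracle_connected(mem, adj)) next
      llr <- oracle_llr(sum(obs[mem]), sum(E[mem]), N)
      if (llr > best_llr + 1e-9) { best <- sort(mem); best_llr <- llr }
    }
  }
  list(members = best, llr = best_llr)
}

# all connected subsets of a graph containing each possible anchor's
# K-neighbourhood, by brute force (for small maps)
oracle_all_connected_subsets <- function(ids, adj) {
  out <- character(0)
  n <- length(ids)
  for (mask in 1:(2^n - 1)) {
    mem <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (oracle_connected(mem, adj)) out <- c(out, paste(sort(mem), collapse = ","))
  }
  out
}
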