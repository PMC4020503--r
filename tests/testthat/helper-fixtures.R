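# fixtures are built in code; nothing is read from disk

line_map <- function(n = 5, ids = LETTERS[seq_len(n)])
  region_map(ids, seq_len(n), rep(0, n))

random_planar_map <- function(n, seed) {
  set.seed(seed)
  region_map(sprintf("R%02d", seq_len(n)), stats::runif(n), stats::runif(n))
}

grid_map <- function(nx, ny) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  region_map(sprintf("G%02d", seq_len(nx * ny)), g$x, g$y)
}

# expected_counts helper: per-region E, period-collapsed
ec <- function(E, ids, N = sum(E))
  expected_counts(data.frame(region = ids, period = NA_integer_, E = E), N)

# a single-stratum stratified_counts table
sc1 <- function(ids, counts, kind = "cases", period = NA_integer_)
  stratified_counts(data.frame(region = ids, period = period, count = counts),
                    character(), kind)

# draw a conditioned null data set (multinomial over E) as named counts
null_counts <- function(E, ids, N) {
  stats::setNames(as.vector(stats::rmultinom(1, N, E / sum(E))), ids)
}
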