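#' End-to-end purely spatial scan from registry tables
#'
#' Applies the configured region exclusions, indirectly standardizes the
#' stratified cases against the stratified population (per period, so
#' temporal trends are absorbed into E), builds the candidate window
#' family and runs the Poisson scan.
#'
#' @param cases,population `stratified_counts` with shared axes.
#' @param map a `region_map` (adjacency required for `method =
#'   "flexible"`).
#' @param config a [scan_config()].
#' @param method `"circular"` or `"flexible"`.
#' @param adjust_axes covariate axes to adjust for (default: all).
#' @return a `cluster_results`.
#' @export
spatial_scan <- function(cases, population, map, config = scan_config(),
                         method = c("circular", "flexible"),
                         adjust_axes = sc_axes(cases)) {
  method <- match.arg(method)
  prep <- prepare_inputs(cases, population, map, config, adjust_axes)
  windows <- if (method == "circular") {
    circular_windows(prep$map, prep$weights, config$max_population_fraction)
  } else {
    m <- prep$map
    if (is.null(m$adjacency)) m <- build_adjacency(m, "delaunay")
    enumerate_flex_windows(m, config$K)
  }
  scan(prep$observed, prep$expected, windows, config)
}

#' End-to-end space-time analysis from registry tables
#'
#' Runs the joint space-time Poisson + space-time permutation analysis
#' ([spacetime_analysis()]) over cylinders built on circular windows. The
#' Poisson scan's expected counts are computed *without* per-period
#' standardization (temporal structure left in the data), which is what
#' makes the trend-artifact diagnosis informative.
#'
#' @inheritParams spatial_scan
#' @return list with `st`, `stp`, `trend_artifact` (see
#'   [spacetime_analysis()]).
#' @export
spacetime_scan <- function(cases, population, map, config = scan_config(),
                           adjust_axes = sc_axes(cases)) {
  prep <- prepare_inputs(cases, population, map, config, adjust_axes,
                         by_period = FALSE)
  windows <- circular_windows(prep$map, prep$weights,
                              config$max_population_fraction)
  periods <- sc_periods(prep$cases)
  cyl <- cylinders(windows, periods, config$max_time_fraction)
  obs <- as_region_period_matrix(prep$cases, region_ids(prep$map), periods)
  spacetime_analysis(obs, prep$expected, cyl, config)
}

prepare_inputs <- function(cases, population, map, config, adjust_axes,
                           by_period = TRUE) {
  excl <- config$excluded_regions
  if (length(excl)) {
    map <- exclude_regions(map, intersect(excl, region_ids(map)))
    cases <- filter_regions(cases, drop = excl)
    population <- filter_regions(population, drop = excl)
  }
  ids <- region_ids(map)
  cases <- filter_regions(cases, keep = ids)
  population <- filter_regions(population, keep = ids)
  expected <- indirect_standardize(cases, population,
                                   adjust_axes = adjust_axes,
                                   by_period = by_period)
  list(map = map, cases = cases, population = population,
       expected = expected,
       observed = region_totals(cases, ids),
       weights = region_totals(population, ids))
}
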