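#' Table-style analysis report
#'
#' Summarises a scan into the registry-study table layout: a study-area
#' column plus one column per reported significant cluster, with rows for
#' population at risk, case count, average annual incidence per 100,000
#' person-years, relative risk, log likelihood ratio and p-value. Every
#' cell is recomputed from the underlying results and inputs.
#'
#' @param results a `cluster_results`.
#' @param cases,population the `stratified_counts` the scan consumed.
#' @param config the [scan_config()] used (significance threshold, R).
#' @param study_years person-year multiplier; defaults to the number of
#'   periods in the case table (1 if the cases carry no periods).
#' @param label report heading.
#' @return object of class `analysis_report`: list with a `table`
#'   data.frame (machine readable, full precision) and print metadata.
#' @export
summarize_scan <- function(results, cases, population,
                           config = attr(results, "config"),
                           study_years = NULL, label = "spatial scan") {
  periods <- sc_periods(cases)
  if (is.null(study_years))
    study_years <- if (length(periods)) length(periods) else 1L
  pop_reg <- region_totals(population)
  # period-stratified populations are person-years; report annual persons
  if (length(sc_periods(population)))
    pop_reg <- pop_reg / length(sc_periods(population))
  cas_reg <- region_totals(cases)
  N <- sum(cas_reg); Ptot <- sum(pop_reg)

  cols <- list(data.frame(
    column = "study area", members = I(list(names(pop_reg))),
    population = Ptot, cases = N,
    annual_rate_per_100k = annual_rate_per_100k(N, Ptot, study_years),
    rr = NA_real_, llr = NA_real_, p_mc = NA_real_,
    stringsAsFactors = FALSE))
  sig <- which(results$p_mc <= config$alpha)
  for (i in sig) {
    mem <- results$members[[i]]
    popc <- sum(pop_reg[mem])
    cols[[length(cols) + 1L]] <- data.frame(
      column = sprintf("cluster %d", results$rank[i]),
      members = I(list(mem)),
      population = popc, cases = results$n[i],
      annual_rate_per_100k = annual_rate_per_100k(results$n[i], popc, study_years),
      rr = results$rr[i], llr = results$llr[i], p_mc = results$p_mc[i],
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, cols), label = label,
                 study_years = study_years, alpha = config$alpha,
                 replicates = config$replicates),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  t <- x$table
  cat(sprintf("== %s (study span %d years, R = %d) ==\n",
              x$label, x$study_years, x$replicates))
  fmt <- function(v, d) ifelse(is.na(v), "", formatC(v, format = "f", digits = d))
  out <- data.frame(
    column = t$column,
    population = formatC(t$population, format = "d", big.mark = ","),
    cases = formatC(t$cases, format = "d", big.mark = ","),
    `annual/100k` = fmt(t$annual_rate_per_100k, 1),
    RR = fmt(t$rr, 2), LLR = fmt(t$llr, 2),
    p = vapply(t$p_mc, function(p)
      if (is.na(p)) "" else format_pvalue(p, x$replicates), ""),
    check.names = FALSE)
  print(out, row.names = FALSE)
  if (nrow(t) == 1) cat("  (no significant clusters)\n")
  invisible(x)
}

#' Stratified and covariate-subset reruns
#'
#' Reruns the full purely spatial analysis either separately per level of
#' a stratum axis (the level's counts only, that axis dropped from the
#' adjustment — e.g. a females-only scan adjusted for the remaining
#' covariates) or on the full data with a reduced adjustment-axis set
#' (e.g. adjust age and sex but not race).
#'
#' @inheritParams spatial_scan
#' @param split_axis stratum axis to analyse level-by-level, or `NULL`.
#' @param levels levels of `split_axis` to run (default: all).
#' @param adjust_axes adjustment axes for a covariate-subset rerun (used
#'   when `split_axis` is `NULL`).
#' @return named list of `analysis_report`s (one per level), or a single
#'   report for a covariate-subset rerun.
#' @export
stratified_rerun <- function(cases, population, map, config = scan_config(),
                             split_axis = NULL, levels = NULL,
                             adjust_axes = sc_axes(cases),
                             method = "circular") {
  if (is.null(split_axis)) {
    res <- spatial_scan(cases, population, map, config, method,
                        adjust_axes = adjust_axes)
    return(summarize_scan(res, cases, population, config,
                          label = sprintf("spatial scan (adjusted: %s)",
                                          paste(adjust_axes, collapse = ", "))))
  }
  if (!split_axis %in% sc_axes(cases)) stop("unknown axis: ", split_axis)
  if (is.null(levels)) levels <- sort(unique(cases[[split_axis]]))
  out <- list()
  for (lv in levels) {
    ca <- cases[cases[[split_axis]] == lv, , drop = FALSE]
    po <- population[population[[split_axis]] == lv, , drop = FALSE]
    if (!nrow(ca) || sum(ca$count) == 0)
      stop("empty stratum after filtering: ", split_axis, " = ", lv)
    keep_axes <- setdiff(sc_axes(cases), split_axis)
    ca <- stratified_counts(ca, keep_axes, "cases")
    po <- stratified_counts(po, keep_axes, "population")
    res <- spatial_scan(ca, po, map, config, method)
    out[[lv]] <- summarize_scan(res, ca, po, config,
                                label = sprintf("spatial scan, %s = %s",
                                                split_axis, lv))
  }
  out
}

#' Export scan results as a GeoJSON FeatureCollection
#'
#' One point feature per region with properties `id`, `cluster` (the
#' reported cluster rank, or `"none"`), `rr` and `p` of the covering
#' cluster. Replaces cartographic output with a portable overlay.
#'
#' @param results a `cluster_results`.
#' @param map the `region_map` scanned.
#' @param file optional path; when given the JSON is written there.
#' @param alpha only clusters with `p_mc <= alpha` are labelled
#'   (default: the scan's configured alpha).
#' @return the FeatureCollection as a list (invisibly if written).
#' @export
export_geojson <- function(results, map, file = NULL,
                           alpha = attr(results, "config")$alpha) {
  r <- map$regions
  cluster <- rep("none", nrow(r))
  rr <- rep(NA_real_, nrow(r)); p <- rep(NA_real_, nrow(r))
  sig <- which(results$p_mc <= alpha)
  for (i in sig) {
    j <- match(results$members[[i]], r$id)
    cluster[j] <- as.character(results$rank[i])
    rr[j] <- results$rr[i]; p[j] <- results$p_mc[i]
  }
  # GeoJSON positions are [longitude, latitude]
  coords <- if (map$mode == "latlong") cbind(r$y, r$x) else cbind(r$x, r$y)
  features <- lapply(seq_len(nrow(r)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(coords[i, 1], coords[i, 2])),
         properties = list(id = r$id[i], cluster = cluster[i],
                           rr = if (is.na(rr[i])) NULL else rr[i],
                           p = if (is.na(p[i])) NULL else p[i]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(file)) {
    jsonlite::write_json(fc, file, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(fc))
  }
  fc
}
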