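#' Stratified case or population counts
#'
#' The registry model: nonnegative integer counts indexed by region,
#' stratum (a tuple over declared axes such as age group, sex, race) and
#' period (calendar year). A population table may carry `NA` periods,
#' meaning the counts are constant across the study periods.
#'
#' @param df data.frame with columns `region`, `count`, optionally
#'   `period`, plus one column per stratum axis.
#' @param axes character vector naming the stratum-axis columns (may be
#'   empty for unstratified counts).
#' @param kind `"cases"` or `"population"`.
#' @return object of class `stratified_counts` (a data.frame).
#' @export
stratified_counts <- function(df, axes = character(), kind = c("cases", "population")) {
  kind <- match.arg(kind)
  df <- as.data.frame(df)
  need <- c("region", axes, "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"period" %in% names(df)) df$period <- NA_integer_
  df <- df[, c("region", "period", axes, "count")]
  df$region <- as.character(df$region)
  if (any(!is.finite(df$count)) || any(df$count < 0))
    stop("counts must be nonnegative and finite")
  if (any(df$count != round(df$count)))
    stop("counts must be integers")
  for (a in axes) df[[a]] <- as.character(df[[a]])
  structure(df, axes = axes, kind = kind,
            class = c("stratified_counts", "data.frame"))
}

#' @export
print.stratified_counts <- function(x, ...) {
  cat(sprintf("<stratified_counts: %s> %d rows, axes: %s, total = %s\n",
              attr(x, "kind"), nrow(x),
              if (length(attr(x, "axes"))) paste(attr(x, "axes"), collapse = " x ")
              else "(none)",
              format(sum(x$count))))
  invisible(x)
}

sc_axes <- function(x) attr(x, "axes")

sc_periods <- function(x) {
  p <- unique(x$period)
  sort(p[!is.na(p)])
}

# aggregate counts to a named per-region vector (optionally filtered)
region_totals <- function(x, regions = NULL) {
  t <- tapply(x$count, x$region, sum)
  v <- stats::setNames(as.numeric(t), names(t))
  if (!is.null(regions)) {
    out <- stats::setNames(numeric(length(regions)), regions)
    out[names(v)[names(v) %in% regions]] <- v[names(v) %in% regions]
    v <- out
  }
  v
}

# replicate NA-period rows over the declared periods
expand_periods <- function(x, periods) {
  isna <- is.na(x$period)
  if (!any(isna)) return(x)
  if (!length(periods)) return(x)
  con <- x[isna, , drop = FALSE]
  rep_rows <- con[rep(seq_len(nrow(con)), each = length(periods)), , drop = FALSE]
  rep_rows$period <- rep(periods, times = nrow(con))
  out <- rbind(x[!isna, , drop = FALSE], rep_rows)
  attributes(out)[c("axes", "kind", "class")] <-
    attributes(x)[c("axes", "kind", "class")]
  out
}

# restrict to a subset of regions / drop excluded ones
filter_regions <- function(x, keep = NULL, drop = NULL) {
  sel <- rep(TRUE, nrow(x))
  if (!is.null(keep)) sel <- sel & x$region %in% keep
  if (!is.null(drop)) sel <- sel & !(x$region %in% drop)
  out <- x[sel, , drop = FALSE]
  attributes(out)[c("axes", "kind", "class")] <-
    attributes(x)[c("axes", "kind", "class")]
  out
}

#' Expected counts under the constant-risk null
#'
#' @param df data.frame with columns `region`, `period` (may be `NA`) and `E`.
#' @param N total observed case count the expectations are conditioned on.
#' @return object of class `expected_counts`.
#' @export
expected_counts <- function(df, N) {
  df <- as.data.frame(df)[, c("region", "period", "E")]
  if (any(df$E < 0)) stop("expected counts must be nonnegative")
  structure(df, N = as.numeric(N),
            class = c("expected_counts", "data.frame"))
}

#' @export
print.expected_counts <- function(x, ...) {
  cat(sprintf("<expected_counts> %d cells, N = %s, sum(E) = %.6g\n",
              nrow(x), format(attr(x, "N")), sum(x$E)))
  invisible(x)
}

#' Total observed cases an `expected_counts` object is conditioned on
#' @param e an `expected_counts` object.
#' @return numeric N.
#' @export
expected_total <- function(e) attr(e, "N")

# per-region E collapsed over periods, as a named vector aligned to `regions`
expected_by_region <- function(e, regions) {
  t <- tapply(e$E, e$region, sum)
  out <- stats::setNames(numeric(length(regions)), regions)
  out[names(t)] <- as.numeric(t)
  out
}

#' Indirect standardization: covariate-adjusted expected counts
#'
#' Computes each region's expected case count under the null hypothesis
#' that stratum-specific risk is constant across the map: for region i,
#' `E_i = sum_s P_{i,s} * (C_s / P_s)` where `C_s`, `P_s` are study-wide
#' stratum totals over the adjustment axes (axes not adjusted for are
#' collapsed first). By construction `sum(E) = N`, the total case count,
#' so the scans operate conditionally on N.
#'
#' When both tables carry periods and `by_period = TRUE`, stratum rates are
#' computed per (stratum x period), so purely temporal trends are absorbed
#' into E — the temporal analogue of the covariate adjustment.
#'
#' @param cases,population `stratified_counts` with identical stratum axes.
#' @param adjust_axes axes to adjust for (default: all shared axes); the
#'   empty set reduces to allocation proportional to total population.
#' @param by_period compute rates per period when periods are present.
#' @return an `expected_counts` object, one row per region (x period when
#'   `by_period` and periods exist).
#' @export
indirect_standardize <- function(cases, population,
                                 adjust_axes = sc_axes(cases),
                                 by_period = TRUE) {
  if (!setequal(sc_axes(cases), sc_axes(population)))
    stop("cases and population must share identical stratum axes")
  bad <- setdiff(adjust_axes, sc_axes(cases))
  if (length(bad))
    stop("unknown adjustment axis(es): ", paste(bad, collapse = ", "))
  N <- sum(cases$count)
  if (N <= 0) stop("total case count must be positive")

  periods <- sc_periods(cases)
  use_period <- by_period && length(periods) > 0
  pop <- expand_periods(population, periods)
  cas <- expand_periods(cases, periods)

  strat_key <- function(d) {
    parts <- lapply(adjust_axes, function(a) d[[a]])
    if (use_period) parts <- c(parts, list(d$period))
    if (!length(parts)) return(rep("all", nrow(d)))
    do.call(paste, c(parts, sep = "\r"))
  }
  ck <- strat_key(cas); pk <- strat_key(pop)
  C_s <- tapply(cas$count, ck, sum)
  P_s <- tapply(pop$count, pk, sum)
  # strata with cases need population to carry them
  no_pop <- names(C_s)[C_s > 0 & !(names(C_s) %in% names(P_s)[P_s > 0])]
  if (length(no_pop))
    stop("stratum with cases but zero population: ",
         paste(gsub("\r", "/", no_pop), collapse = "; "))
  rate <- stats::setNames(rep(0, length(P_s)), names(P_s))
  pos <- P_s > 0
  rate[pos] <- ifelse(names(P_s)[pos] %in% names(C_s),
                      C_s[match(names(P_s)[pos], names(C_s))] / P_s[pos], 0)
  rate[is.na(rate)] <- 0   # strata with population but no case stratum: 0

  pop$E_part <- pop$count * rate[pk]
  grp <- if (use_period) paste(pop$region, pop$period, sep = "\r") else pop$region
  E <- tapply(pop$E_part, grp, sum)
  if (use_period) {
    parts <- strsplit(names(E), "\r", fixed = TRUE)
    df <- data.frame(region = vapply(parts, `[[`, "", 1L),
                     period = as.integer(vapply(parts, `[[`, "", 2L)),
                     E = as.numeric(E), stringsAsFactors = FALSE)
  } else {
    df <- data.frame(region = names(E), period = NA_integer_,
                     E = as.numeric(E), stringsAsFactors = FALSE)
  }
  expected_counts(df, N)
}

#' Average annual incidence rate per 100,000 person-years
#'
#' @param cases case count.
#' @param population population at risk (persons).
#' @param years study-span length in years (the denominator is
#'   `population * years` person-years).
#' @return rate per 100,000 person-years.
#' @export
annual_rate_per_100k <- function(cases, population, years) {
  if (any(population <= 0)) stop("population must be positive")
  if (any(years < 1)) stop("years must be >= 1")
  if (any(cases < 0)) stop("cases must be nonnegative")
  cases / (population * years) * 1e5
}

#' Per-period incidence rate series
#'
#' One annualised rate per period (years = 1 per period), e.g. for
#' plotting a statewide incidence trend.
#'
#' @param cases,population `stratified_counts`; population may be
#'   period-constant (`NA` periods).
#' @return data.frame with `period` and `rate` (per 100,000).
#' @export
annual_rates_by_period <- function(cases, population) {
  periods <- sc_periods(cases)
  if (!length(periods)) stop("cases carry no periods")
  pop <- expand_periods(population, periods)
  pt <- tapply(pop$count, pop$period, sum)
  missing_p <- setdiff(as.character(periods), names(pt))
  if (length(missing_p))
    stop("population missing for period(s): ", paste(missing_p, collapse = ", "))
  ct <- tapply(cases$count, cases$period, sum)
  cs <- stats::setNames(rep(0, length(periods)), as.character(periods))
  cs[names(ct)] <- as.numeric(ct)
  data.frame(period = periods,
             rate = annual_rate_per_100k(as.numeric(cs[as.character(periods)]),
                                         as.numeric(pt[as.character(periods)]),
                                         1))
}

# case/population file dialect ------------------------------------------------

#' Read a case file
#'
#' Dialect (SaTScan-style): `id count [period covariate...]`, whitespace
#' delimited, `#` comments and blank lines ignored. The covariate columns
#' are named by `axes`, in order.
#'
#' @param path file path or connection.
#' @param axes names for the trailing covariate columns (may be empty).
#' @param has_period whether a period (year) field follows the count.
#' @return a `stratified_counts` of kind `"cases"`.
#' @export
read_cases <- function(path, axes = character(), has_period = TRUE) {
  nf <- 2L + as.integer(has_period) + length(axes)
  recs <- parse_table_lines(readLines(path), nf, "case")
  df <- data.frame(region = vapply(recs, `[[`, "", 1L),
                   count = parse_num_field(recs, 2L, "case"),
                   stringsAsFactors = FALSE)
  j <- 3L
  if (has_period) { df$period <- as.integer(parse_num_field(recs, j, "case")); j <- j + 1L }
  for (a in axes) { df[[a]] <- vapply(recs, `[[`, "", j); j <- j + 1L }
  stratified_counts(df, axes, "cases")
}

#' Read a population file
#'
#' Dialect: `id period count covariate...`; a period field of `all` maps to
#' a period-constant population.
#'
#' @inheritParams read_cases
#' @return a `stratified_counts` of kind `"population"`.
#' @export
read_population <- function(path, axes = character()) {
  nf <- 3L + length(axes)
  recs <- parse_table_lines(readLines(path), nf, "population")
  praw <- vapply(recs, `[[`, "", 2L)
  period <- suppressWarnings(as.integer(praw))
  if (any(is.na(period) & tolower(praw) != "all"))
    stop("population file: period must be an integer year or 'all'")
  df <- data.frame(region = vapply(recs, `[[`, "", 1L),
                   period = period,
                   count = parse_num_field(recs, 3L, "population"),
                   stringsAsFactors = FALSE)
  j <- 4L
  for (a in axes) { df[[a]] <- vapply(recs, `[[`, "", j); j <- j + 1L }
  stratified_counts(df, axes, "population")
}

#' Write case / population files in the package dialect
#' @param x a `stratified_counts`.
#' @param path output path or connection.
#' @return `path`, invisibly.
#' @export
write_cases <- function(x, path) {
  axes <- sc_axes(x)
  cov <- if (length(axes)) do.call(paste, x[axes]) else ""
  per <- ifelse(is.na(x$period), "all", as.character(x$period))
  writeLines(trimws(paste(x$region, x$count, per, cov)), path)
  invisible(path)
}

#' @rdname write_cases
#' @export
write_population <- function(x, path) {
  axes <- sc_axes(x)
  cov <- if (length(axes)) do.call(paste, x[axes]) else ""
  per <- ifelse(is.na(x$period), "all", as.character(x$period))
  writeLines(trimws(paste(x$region, per, x$count, cov)), path)
  invisible(path)
}
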