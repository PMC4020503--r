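#' Region map: centroids and adjacency for a set of areal units
#'
#' A `region_map` holds the spatial substrate every scan operates on: one
#' centroid per region (projected planar km or lat/long, declared explicitly)
#' and, optionally, a symmetric adjacency relation used by the flexibly
#' shaped scan's connectivity constraint.
#'
#' @param ids character or integer vector of unique region labels.
#' @param x,y numeric centroid coordinates. In `"latlong"` mode `x` is the
#'   latitude and `y` the longitude, matching the column order of the
#'   coordinates file dialect (id, lat, long).
#' @param mode coordinate mode, `"planar"` or `"latlong"`. Never inferred.
#' @param adjacency optional two-column matrix/data.frame of region-id pairs;
#'   stored symmetric and irreflexive.
#' @return An object of class `region_map`.
#' @export
region_map <- function(ids, x, y, mode = c("planar", "latlong"),
                       adjacency = NULL) {
  mode <- match.arg(mode)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate region id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(ids) || length(y) != length(ids))
    stop("ids, x, y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all centroid coordinates must be finite")
  if (mode == "latlong" &&
      (any(abs(x) > 90) || any(abs(y) > 180)))
    stop("latlong mode: latitude must lie in [-90, 90], longitude in [-180, 180]")
  m <- structure(
    list(regions = data.frame(id = ids, x = x, y = y,
                              stringsAsFactors = FALSE),
         mode = mode, adjacency = NULL),
    class = "region_map")
  if (!is.null(adjacency)) m <- set_adjacency(m, adjacency)
  m
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d regions, %s coordinates, %s\n",
              nrow(x$regions), x$mode,
              if (is.null(x$adjacency)) "no adjacency"
              else sprintf("%d adjacency edges", nrow(x$adjacency))))
  invisible(x)
}

#' Number of regions in a map
#' @param map a `region_map`.
#' @return integer count.
#' @export
n_regions <- function(map) nrow(map$regions)

#' Region ids of a map
#' @param map a `region_map`.
#' @return character vector.
#' @export
region_ids <- function(map) map$regions$id

set_adjacency <- function(map, edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("adjacency must have two columns")
  storage.mode(edges) <- "character"
  ids <- region_ids(map)
  unknown <- setdiff(c(edges), ids)
  if (length(unknown))
    stop("adjacency references unknown region(s): ",
         paste(unknown, collapse = ", "))
  if (any(edges[, 1] == edges[, 2]))
    stop("adjacency must be irreflexive (self-loop found)")
  # canonical undirected storage: sorted within pair, deduplicated
  a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  e <- cbind(a = a[keep], b = b[keep])
  map$adjacency <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  map
}

#' Adjacency list (region id -> neighbouring ids)
#' @param map a `region_map` with adjacency.
#' @return named list of character vectors.
#' @export
adjacency_list <- function(map) {
  if (is.null(map$adjacency)) stop("map has no adjacency; call build_adjacency()")
  ids <- region_ids(map)
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) out[[i]] <- character()
  e <- map$adjacency
  for (k in seq_len(nrow(e))) {
    out[[e[k, 1]]] <- c(out[[e[k, 1]]], e[k, 2])
    out[[e[k, 2]]] <- c(out[[e[k, 2]]], e[k, 1])
  }
  lapply(out, sort)
}

#' Read a whitespace-delimited coordinates file
#'
#' Dialect: one record per region, `id x y` (planar) or `id lat long`
#' (lat/long); blank lines and lines starting with `#` are ignored.
#'
#' @param source path or connection.
#' @param mode `"planar"` or `"latlong"` (explicit, never inferred).
#' @return a `region_map` without adjacency.
#' @export
read_coordinates <- function(source, mode = c("planar", "latlong")) {
  mode <- match.arg(mode)
  lines <- readLines(source)
  recs <- parse_table_lines(lines, 3L, "coordinates")
  region_map(ids = vapply(recs, `[[`, "", 1L),
             x = parse_num_field(recs, 2L, "coordinates"),
             y = parse_num_field(recs, 3L, "coordinates"),
             mode = mode)
}

#' Write a coordinates file (full precision round-trip)
#' @param map a `region_map`.
#' @param path output path or connection.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(map, path) {
  r <- map$regions
  writeLines(sprintf("%s %.17g %.17g", r$id, r$x, r$y), path)
  invisible(path)
}

# shared file-dialect helpers -------------------------------------------------

parse_table_lines <- function(lines, nfields, what) {
  keep <- which(!grepl("^\\s*(#|$)", lines))
  recs <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(recs) != nfields)
  if (length(bad))
    stop(sprintf("%s file: line %d has %d field(s), expected %d",
                 what, keep[bad[1]], lengths(recs)[bad[1]], nfields))
  recs
}

parse_num_field <- function(recs, j, what) {
  v <- suppressWarnings(as.numeric(vapply(recs, `[[`, "", j)))
  if (anyNA(v))
    stop(sprintf("%s file: non-numeric value in field %d", what, j))
  v
}

#' Pairwise centroid distances
#'
#' Euclidean distance in planar mode; great-circle distance (spherical law
#' of cosines, mean Earth radius 6371.0 km) in lat/long mode.
#'
#' @param map a `region_map`.
#' @return symmetric distance matrix with zero diagonal, region ids as
#'   dimnames; kilometres in lat/long mode, coordinate units in planar mode.
#' @export
region_distances <- function(map) {
  r <- map$regions
  if (map$mode == "planar") {
    d <- as.matrix(stats::dist(cbind(r$x, r$y)))
  } else {
    phi <- r$x * pi / 180; lam <- r$y * pi / 180
    cosang <- outer(sin(phi), sin(phi)) +
      outer(cos(phi), cos(phi)) * cos(outer(lam, lam, `-`))
    cosang[] <- pmin(1, pmax(-1, cosang))   # pmin/pmax drop the dim attribute
    d <- 6371.0 * acos(cosang)
    diag(d) <- 0
  }
  dimnames(d) <- list(r$id, r$id)
  d
}

#' Build region adjacency from centroids
#'
#' `"delaunay"`: edges of the Delaunay triangulation, found by the
#' empty-circumcircle test over all point triples (adequate for maps of a
#' few hundred units). Points within tolerance of a circumcircle do not
#' invalidate a triangle, so co-circular ties keep every tied triangle —
#' a deterministic rule. `"knn"`: union of each region's k nearest
#' neighbours, symmetrised.
#'
#' @param map a `region_map`.
#' @param method `"delaunay"` or `"knn"`.
#' @param k neighbour count for `"knn"`.
#' @return the map with adjacency set.
#' @export
build_adjacency <- function(map, method = c("delaunay", "knn"), k = 4L) {
  method <- match.arg(method)
  ids <- region_ids(map)
  n <- length(ids)
  if (method == "knn") {
    if (k < 1 || k > n - 1) stop("knn: k must be in [1, n_regions - 1]")
    D <- region_distances(map)
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      ord <- order(D[i, ], ids)          # ties broken lexicographically
      nb <- setdiff(ids[ord], ids[i])[seq_len(k)]
      cbind(ids[i], nb)
    }))
    return(set_adjacency(map, edges))
  }
  if (n < 3) stop("delaunay: need at least 3 regions")
  if (map$mode != "planar")
    stop("delaunay adjacency requires planar coordinates")
  set_adjacency(map, delaunay_edges(map$regions$x, map$regions$y, ids))
}

# Brute-force Delaunay: a triangle belongs to the triangulation iff its
# circumcircle contains no other point strictly inside (tolerance-relative).
delaunay_edges <- function(x, y, ids) {
  n <- length(x)
  scale2 <- max(diff(range(x)), diff(range(y)))^2
  eps <- 1e-9 * scale2
  tri <- utils::combn(n, 3)
  edges <- vector("list", ncol(tri))
  m <- 0L
  for (t in seq_len(ncol(tri))) {
    i <- tri[1, t]; j <- tri[2, t]; k <- tri[3, t]
    # circumcentre via perpendicular-bisector solve
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12 * scale2) next   # collinear triple, no circumcircle
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (x - ux)^2 + (y - uy)^2
    d2[c(i, j, k)] <- Inf
    if (all(d2 > r2 - eps)) {
      m <- m + 1L
      edges[[m]] <- cbind(ids[c(i, i, j)], ids[c(j, k, k)])
    }
  }
  if (m == 0L) stop("delaunay: degenerate geometry (all points collinear?)")
  do.call(rbind, edges[seq_len(m)])
}

#' Drop regions from a map (pre-analysis exclusion)
#'
#' Supports study designs that exclude particular units up front (for
#' example a county whose case load is institutional rather than
#' residential). Adjacency edges touching excluded regions are dropped.
#'
#' @param map a `region_map`.
#' @param ids region ids to remove; unknown ids are an error.
#' @return the reduced map.
#' @export
exclude_regions <- function(map, ids) {
  ids <- as.character(ids)
  if (!length(ids)) return(map)
  unknown <- setdiff(ids, region_ids(map))
  if (length(unknown))
    stop("cannot exclude unknown region(s): ", paste(unknown, collapse = ", "))
  keep <- !(map$regions$id %in% ids)
  adj <- map$adjacency
  map$regions <- map$regions[keep, , drop = FALSE]
  rownames(map$regions) <- NULL
  map$adjacency <- NULL
  if (!is.null(adj)) {
    adj <- adj[!(adj[, 1] %in% ids) & !(adj[, 2] %in% ids), , drop = FALSE]
    if (nrow(adj)) map <- set_adjacency(map, adj)
  }
  map
}

# connected components by BFS over the adjacency list
graph_components <- function(map) {
  al <- adjacency_list(map)
  ids <- region_ids(map)
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  cur <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- cur
      queue <- c(queue, al[[v]][is.na(comp[al[[v]]])])
    }
  }
  comp
}
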