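#' Dyadic spatial-interaction dataset
#'
#' Container for a directed dyad dataset: a set of locations (with user
#' populations and either coordinates or a supplied pairwise distance
#' matrix) and directed source--destination interaction counts. The
#' outcome modelled throughout the package is the natural log of the
#' count, `y = log(count)`; pairs with a zero count are dropped at
#' construction with a warning, since the log outcome is undefined there
#' and adding a small constant is known to bias the fit.
#'
#' @param locations data.frame with columns `id`, `population`, and
#'   (unless `dist` is supplied) `lat`, `lon` in decimal degrees.
#' @param pairs data.frame with columns `src`, `dst`, `count`; `src` and
#'   `dst` must match `locations$id`, self-pairs are not allowed.
#' @param dist optional square distance matrix in kilometres with
#'   dimnames equal to the location ids. When both coordinates and a
#'   matrix are given the matrix wins; discrepancies beyond 1 km against
#'   the haversine distances are reported via `message()`.
#'
#' @return An object of class `dyad_data`: a list with elements
#'   `locations` (with an added `log_pop` column), `pairs` (columns `i`,
#'   `j` (location indices), `src`, `dst`, `d` (km), `log_d`, `count`,
#'   `y`), `S` (number of locations) and `dist` (full S x S km matrix).
#'   Pairs are sorted by (source index, destination index) so that all
#'   design matrices built from the object have a reproducible row order.
#' @export
dyad_data <- function(locations, pairs, dist = NULL) {
  locations <- as.data.frame(locations)
  pairs <- as.data.frame(pairs)
  req_loc <- c("id", "population")
  if (!all(req_loc %in% names(locations)))
    stop("locations must have columns: ", paste(req_loc, collapse = ", "))
  if (!all(c("src", "dst", "count") %in% names(pairs)))
    stop("pairs must have columns: src, dst, count")
  if (anyDuplicated(locations$id))
    stop("duplicate location ids")
  if (any(locations$population < 1))
    stop("populations must be >= 1")
  if (!is.null(locations$lat) &&
      any(locations$lat < -90 | locations$lat > 90))
    stop("latitude outside [-90, 90]")
  if (!is.null(locations$lon) &&
      any(locations$lon < -180 | locations$lon > 180))
    stop("longitude outside [-180, 180]")

  S <- nrow(locations)
  ids <- as.character(locations$id)

  i <- match(as.character(pairs$src), ids)
  j <- match(as.character(pairs$dst), ids)
  if (anyNA(i) || anyNA(j))
    stop("pair table references unknown location ids: ",
         paste(unique(c(pairs$src[is.na(i)], pairs$dst[is.na(j)])),
               collapse = ", "))
  if (any(i == j)) stop("self-pairs (src == dst) are not allowed")
  if (any(pairs$count < 0)) stop("negative counts")

  dmat <- resolve_distances(locations, dist)

  drop <- pairs$count == 0
  if (any(drop)) {
    warning(sum(drop), " pair(s) with zero count dropped ",
            "(log outcome undefined)")
    pairs <- pairs[!drop, , drop = FALSE]
    i <- i[!drop]; j <- j[!drop]
  }
  if (anyDuplicated(cbind(i, j))) stop("duplicate (src, dst) pairs")

  d <- dmat[cbind(i, j)]
  if (any(d <= 0)) stop("non-positive pairwise distance for retained pair")

  out <- data.frame(
    i = i, j = j,
    src = as.character(pairs$src), dst = as.character(pairs$dst),
    d = d, log_d = log(d),
    count = pairs$count, y = log(pairs$count),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  locations$log_pop <- log(locations$population)

  structure(
    list(locations = locations, pairs = out, S = S, dist = dmat),
    class = "dyad_data"
  )
}

# Distance matrix from a supplied km matrix or from haversine on centroids.
resolve_distances <- function(locations, dist) {
  ids <- as.character(locations$id)
  S <- length(ids)
  have_coords <- !is.null(locations$lat) && !is.null(locations$lon) &&
    !anyNA(locations$lat) && !anyNA(locations$lon)
  if (!is.null(dist)) {
    dist <- as.matrix(dist)
    if (nrow(dist) != S || ncol(dist) != S)
      stop("distance matrix must be ", S, " x ", S)
    if (!is.null(rownames(dist))) {
      if (!setequal(rownames(dist), ids))
        stop("distance matrix ids do not match location ids")
      dist <- dist[ids, ids]
    }
    if (have_coords) {
      hv <- haversine_matrix(locations$lat, locations$lon)
      mism <- abs(hv - dist) > 1
      diag(mism) <- FALSE
      if (any(mism))
        message(sum(mism) / 2, " pair distance(s) differ from haversine ",
                "by > 1 km; supplied matrix used")
    }
    dimnames(dist) <- list(ids, ids)
    return(dist)
  }
  if (!have_coords)
    stop("need either lat/lon coordinates or a distance matrix")
  dm <- haversine_matrix(locations$lat, locations$lon)
  dimnames(dm) <- list(ids, ids)
  dm
}

#' Great-circle distance matrix
#'
#' Haversine distances between all pairs of points, in kilometres, on a
#' sphere of radius 6371 km.
#'
#' @param lat,lon numeric vectors of decimal degrees.
#' @return symmetric matrix of distances in km with zero diagonal.
#' @export
haversine_matrix <- function(lat, lon) {
  p <- cbind(lon, lat)
  n <- nrow(p)
  m <- matrix(0, n, n)
  for (k in seq_len(n)) {
    m[k, ] <- geosphere::distHaversine(p[k, , drop = FALSE], p,
                                       r = 6371000) / 1000
  }
  (m + t(m)) / 2
}

#' @export
print.dyad_data <- function(x, ...) {
  cat("dyad_data: ", x$S, " locations, ", nrow(x$pairs),
      " directed pairs\n", sep = "")
  cat("  populations: [", min(x$locations$population), ", ",
      max(x$locations$population), "]\n", sep = "")
  cat("  distances (km): [", signif(min(x$pairs$d), 4), ", ",
      signif(max(x$pairs$d), 4), "]\n", sep = "")
  invisible(x)
}

# Row indices of each source's pairs, precomputed once per dataset.
source_rows <- function(data) {
  split(seq_len(nrow(data$pairs)), factor(data$pairs$i, levels = seq_len(data$S)))
}

# Open range of observed log distances for one source.
theta_range <- function(data, i) {
  ld <- data$pairs$log_d[data$pairs$i == i]
  if (length(ld) == 0) stop("source ", i, " has no pairs")
  range(ld)
}
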