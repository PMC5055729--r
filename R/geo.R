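# Geographic cluster areas: density-based clustering (DBSCAN) of tweet
# coordinates under great-circle distance, convex hulls around the clusters,
# and point-in-hull assignment with a reserved noise cluster.
#
# Label conventions: cluster ids are 1, 2, ...; 0 is the noise label/sink.

NOISE_ID <- 0L

haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

#' DBSCAN over geographic points
#'
#' Standard DBSCAN with great-circle (haversine) distances in kilometres.
#' Core points have at least `min_points` neighbours (themselves included)
#' within `eps_km`; clusters are maximal density-connected sets. Points are
#' processed in input order and neighbourhood expansion is FIFO in index
#' order, so a border point reachable from several clusters deterministically
#' joins the first cluster that reaches it under this scan order.
#' Non-reachable points get the noise label 0.
#'
#' @param points two-column matrix or data.frame of (lat, lon) in decimal
#'   degrees.
#' @param eps_km neighbourhood radius, km.
#' @param min_points core-point density threshold (neighbours within
#'   `eps_km`, the point itself included).
#' @return integer vector of labels (0 = noise, clusters numbered from 1 in
#'   order of discovery).
#' @export
dbscan_geo <- function(points, eps_km, min_points) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n == 0) return(integer())
  stopifnot(eps_km > 0, min_points >= 1)
  lat <- pts[, 1]
  lon <- pts[, 2]

  region_query <- function(i) {
    # coarse bounding-box prefilter, then exact haversine
    dlat <- eps_km / 110.574
    dlon <- eps_km / (111.320 * pmax(cos(lat[i] * pi / 180), 1e-6))
    cand <- which(abs(lat - lat[i]) <= dlat * 1.05 &
                    abs(lon - lon[i]) <= dlon * 1.05)
    cand[haversine_km(lat[i], lon[i], lat[cand], lon[cand]) <= eps_km]
  }

  labels <- rep(NA_integer_, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    nb <- region_query(i)
    if (length(nb) < min_points) {
      labels[i] <- NOISE_ID
      next
    }
    cluster <- cluster + 1L
    labels[i] <- cluster
    queue <- sort(setdiff(nb, i))
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]
      head <- head + 1L
      if (!is.na(labels[j]) && labels[j] == NOISE_ID) {
        labels[j] <- cluster  # border point: noise reclaimed by this cluster
      }
      if (!is.na(labels[j])) next
      labels[j] <- cluster
      nbj <- region_query(j)
      if (length(nbj) >= min_points) {
        queue <- c(queue, sort(setdiff(nbj, queue)))
      }
    }
  }
  labels
}

hull_ccw <- function(hull) {
  # shoelace on the (lon, lat) plane; positive = counter-clockwise
  x <- hull[, "lon"]
  y <- hull[, "lat"]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) hull[rev(seq_len(nrow(hull))), , drop = FALSE] else hull
}

#' Build a cluster model of convex-hull areas
#'
#' One convex hull per non-noise cluster label. Clusters with fewer than three
#' distinct points, or with all points collinear, cannot form a polygon and
#' are dropped with a warning. Hull vertices are returned in counter-clockwise
#' order; areas are geodesic, in square kilometres.
#'
#' @param points two-column matrix or data.frame of (lat, lon).
#' @param labels integer labels from [dbscan_geo()] over the same points.
#' @param names optional named character vector mapping cluster id to label
#'   text (defaults to `"cluster <id>"`).
#' @return an object of class `cluster_model`: a list of clusters
#'   (`cluster_id`, `label`, `hull` matrix, `area_km2`) plus the reserved
#'   `noise_id`.
#' @export
build_cluster_model <- function(points, labels, names = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  colnames(pts) <- c("lat", "lon")
  stopifnot(nrow(pts) == length(labels))
  ids <- sort(unique(labels[labels != NOISE_ID]))
  clusters <- list()
  for (id in ids) {
    sub <- unique(pts[labels == id, , drop = FALSE])
    label_txt <- if (!is.null(names) && !is.null(names[[as.character(id)]])) {
      names[[as.character(id)]]
    } else {
      sprintf("cluster %d", id)
    }
    if (nrow(sub) < 3) {
      warning(sprintf("cluster %d dropped: fewer than 3 distinct points", id),
              call. = FALSE)
      next
    }
    h <- grDevices::chull(sub[, "lon"], sub[, "lat"])
    if (length(h) < 3) {
      warning(sprintf("cluster %d dropped: all points collinear", id),
              call. = FALSE)
      next
    }
    hull <- hull_ccw(sub[h, , drop = FALSE])
    area <- geosphere::areaPolygon(cbind(hull[, "lon"], hull[, "lat"])) / 1e6
    clusters[[length(clusters) + 1L]] <- list(
      cluster_id = as.integer(id), label = label_txt, hull = hull,
      area_km2 = area)
  }
  structure(list(clusters = clusters, noise_id = NOISE_ID),
            class = "cluster_model")
}

point_in_convex_hull <- function(lat, lon, hull, tol = 1e-9) {
  # hull CCW on the (lon, lat) plane: inside iff never to the right of an
  # edge; vectorised over points
  x <- hull[, "lon"]
  y <- hull[, "lat"]
  nx <- c(x[-1], x[1])
  ny <- c(y[-1], y[1])
  inside <- rep(TRUE, length(lat))
  for (e in seq_along(x)) {
    inside <- inside &
      ((nx[e] - x[e]) * (lat - y[e]) - (ny[e] - y[e]) * (lon - x[e]) >= -tol)
    if (!any(inside)) break
  }
  inside
}

#' Assign points to cluster areas
#'
#' Returns the id of the hull containing each point (boundary counts as
#' inside); when several hulls contain a point the smallest-area hull wins;
#' points outside all hulls get the model's noise id.
#'
#' @param points two-column matrix or data.frame of (lat, lon); a single
#'   point may be given as a length-2 vector.
#' @param model a `cluster_model`.
#' @return integer vector of cluster ids (or the noise id).
#' @export
assign_cluster <- function(points, model) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  out <- rep(model$noise_id, nrow(pts))
  if (length(model$clusters) == 0) return(out)
  ord <- order(vapply(model$clusters, `[[`, 0, "area_km2"))
  open <- rep(TRUE, nrow(pts))  # smallest hull checked first, so first hit wins
  for (ci in ord) {
    if (!any(open)) break
    cl <- model$clusters[[ci]]
    idx <- which(open)
    hit <- point_in_convex_hull(pts[idx, 1], pts[idx, 2], cl$hull)
    out[idx[hit]] <- cl$cluster_id
    open[idx[hit]] <- FALSE
  }
  out
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Cluster model: %d convex-hull areas (noise id %d)\n",
              length(x$clusters), x$noise_id))
  for (cl in x$clusters) {
    cat(sprintf("  [%d] %s: %d vertices, %.1f km^2\n", cl$cluster_id,
                cl$label, nrow(cl$hull), cl$area_km2))
  }
  invisible(x)
}
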