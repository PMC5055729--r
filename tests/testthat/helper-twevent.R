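# Shared builders and independent reference implementations (oracles) used
# across the test files. Oracles are deliberately written as plain
# brute-force code, independent of the package's implementation paths.

make_tweets <- function(texts,
                        times = NULL,
                        users = NULL,
                        lat = 52, lon = -1.5,
                        ids = NULL) {
  n <- length(texts)
  if (is.null(times)) {
    times <- as.POSIXct("2014-04-02 10:00:00", tz = "UTC") + seq_len(n) * 60
  }
  data.frame(
    id = if (is.null(ids)) sprintf("t%03d", seq_len(n)) else ids,
    timestamp = as.POSIXct(times, tz = "UTC"),
    user_id = if (is.null(users)) sprintf("u%03d", seq_len(n)) else users,
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    text = texts, is_retweet = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

make_groups <- function(...) {
  specs <- list(...)
  groups <- lapply(names(specs), function(p) {
    list(primary = p, aliases = specs[[p]], event_class = "symptom")
  })
  names(groups) <- names(specs)
  groups
}

# one square-ish cluster model around (lat0, lon0), side ~2*half_deg degrees
make_square_model <- function(lat0 = 52, lon0 = -1.5, half_deg = 0.5) {
  pts <- rbind(c(lat0 - half_deg, lon0 - half_deg),
               c(lat0 - half_deg, lon0 + half_deg),
               c(lat0 + half_deg, lon0 + half_deg),
               c(lat0 + half_deg, lon0 - half_deg))
  build_cluster_model(pts, rep(1L, 4))
}

# --- oracles ----------------------------------------------------------------

oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6378137 / 1000
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# quadratic reference DBSCAN: full distance matrix + FIFO expansion in input
# order (same scan-order semantics, independent code)
oracle_dbscan <- function(pts, eps_km, min_points) {
  n <- nrow(pts)
  if (n == 0) return(integer())
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    oracle_haversine_km(pts[i, 1], pts[i, 2], pts[j, 1], pts[j, 2]))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps_km))
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    if (length(nb[[i]]) < min_points) {
      labels[i] <- 0L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- sort(setdiff(nb[[i]], i))
    pos <- 1L
    while (pos <= length(queue)) {
      j <- queue[pos]
      pos <- pos + 1L
      if (!is.na(labels[j]) && labels[j] == 0L) labels[j] <- cl
      if (!is.na(labels[j])) next
      labels[j] <- cl
      if (length(nb[[j]]) >= min_points) {
        queue <- c(queue, sort(setdiff(nb[[j]], queue)))
      }
    }
  }
  labels
}

# compare two labelings as partitions (cluster ids may differ); noise must
# match exactly
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  key_a <- match(a, unique(a[a != 0L]))
  key_b <- match(b, unique(b[b != 0L]))
  identical(key_a, key_b)
}

# run-length reconstruction of alarms from a logical vector
oracle_runs <- function(alarmed) {
  out <- NULL
  i <- 1L
  n <- length(alarmed)
  while (i <= n) {
    if (alarmed[i]) {
      j <- i
      while (j < n && alarmed[j + 1L]) j <- j + 1L
      out <- rbind(out, c(i, j))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) data.frame(start_idx = integer(), end_idx = integer())
  else data.frame(start_idx = out[, 1], end_idx = out[, 2])
}

# brute-force C2: explicit mean/sd arithmetic per day
oracle_c2 <- function(x, window, k, floor, gap = 0) {
  n <- length(x)
  out <- logical(n)
  for (t in seq_len(n)) {
    lo <- t - gap - window
    hi <- t - gap - 1
    if (lo < 1) next
    b <- x[lo:hi]
    m <- sum(b) / length(b)
    s <- sqrt(sum((b - m)^2) / (length(b) - 1))
    out[t] <- (x[t] - m) > k * max(s, floor)
  }
  out
}

oracle_c3 <- function(c2, lookback, min_alarms) {
  n <- length(c2)
  out <- logical(n)
  for (t in seq_len(n)) {
    cnt <- 0L
    for (s in max(1, t - lookback + 1):t) cnt <- cnt + as.integer(c2[s])
    out[t] <- cnt >= min_alarms
  }
  out
}

# one-sided Fisher tail by explicit binomial-coefficient enumeration
oracle_fisher_p <- function(gw, g, bw, b) {
  k <- gw + bw
  n <- g + b
  hi <- min(k, g)
  if (gw > hi) return(0)
  j <- gw:hi
  sum(exp(lchoose(k, j) + lchoose(n - k, g - j) - lchoose(n, g)))
}

# ray-casting point-in-polygon (counts boundary via tolerance), independent
# of the package's half-plane test
oracle_point_in_poly <- function(lat, lon, hull, tol = 1e-9) {
  x <- hull[, "lon"]
  y <- hull[, "lat"]
  nv <- length(x)
  # boundary check first
  for (e in seq_len(nv)) {
    x1 <- x[e]; y1 <- y[e]
    x2 <- x[e %% nv + 1]; y2 <- y[e %% nv + 1]
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    within <- lon >= min(x1, x2) - tol & lon <= max(x1, x2) + tol &
      lat >= min(y1, y2) - tol & lat <= max(y1, y2) + tol
    if (abs(cross) < 1e-7 && within) return(TRUE)
  }
  inside <- FALSE
  j <- nv
  for (i in seq_len(nv)) {
    if ((y[i] > lat) != (y[j] > lat) &&
        lon < (x[j] - x[i]) * (lat - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
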