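# Daily count series per (keyword group, cluster): raw tweet counts, distinct
# author counts, and counts normalised for the weekly tweeting pattern.

utc_date <- function(ts) as.Date(ts, tz = "UTC")

new_count_series <- function(group_id, cluster_id, days, raw, users,
                             normalised = NULL) {
  stopifnot(length(days) == length(raw), length(raw) == length(users))
  structure(list(group_id = group_id, cluster_id = as.integer(cluster_id),
                 days = days, raw = as.numeric(raw),
                 normalised = if (is.null(normalised)) as.numeric(raw)
                 else as.numeric(normalised),
                 users = as.integer(users)),
            class = "count_series")
}

#' Aggregate matched tweets into daily count series
#'
#' Builds one series per (keyword group, non-noise cluster) pair with at least
#' one matching tweet, zero-filled over the full date range. A tweet matching
#' g groups contributes one count to each of the g series; tweets assigned to
#' the noise cluster are excluded from all series. Normalised counts are
#' initialised to the raw counts; apply [weekday_normalise()] afterwards.
#'
#' @param tweets tweet data.frame (see [read_tweets()]).
#' @param model a `cluster_model`.
#' @param groups keyword groups from [read_keyword_groups()].
#' @param date_range length-2 vector of `Date`s (start, end) covering the
#'   tweets to be counted; defaults to the tweet date span.
#' @return named list of `count_series` objects, keyed `"<group>|<cluster>"`.
#' @export
aggregate_counts <- function(tweets, model, groups, date_range = NULL) {
  if (is.null(date_range)) {
    if (nrow(tweets) == 0) stop("empty tweet set and no date_range",
                                call. = FALSE)
    date_range <- range(utc_date(tweets$timestamp))
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || is.na(date_range[1]) || is.na(date_range[2]) ||
      date_range[1] > date_range[2]) {
    stop("invalid date_range", call. = FALSE)
  }
  days <- seq(date_range[1], date_range[2], by = "day")
  if (nrow(tweets) == 0) return(list())

  cluster <- attr(tweets, "cluster")
  if (is.null(cluster)) cluster <- assign_cluster(cbind(tweets$lat,
                                                        tweets$lon), model)
  matched <- attr(tweets, "matched")
  if (is.null(matched)) matched <- match_groups(tweets$text, groups)
  day <- utc_date(tweets$timestamp)

  keep <- cluster != model$noise_id & lengths(matched) > 0 &
    day >= date_range[1] & day <= date_range[2]
  idx <- which(keep)
  if (length(idx) == 0) return(list())

  # expand to one row per (tweet, matched group)
  reps <- lengths(matched[idx])
  ti <- rep(idx, reps)
  gid <- unlist(matched[idx], use.names = FALSE)
  key <- paste(gid, cluster[ti], sep = "|")

  out <- list()
  for (k in unique(key)) {
    rows <- ti[key == k]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    di <- as.integer(day[rows] - date_range[1]) + 1L
    raw <- tabulate(di, nbins = length(days))
    users <- integer(length(days))
    for (d in unique(di)) {
      users[d] <- length(unique(tweets$user_id[rows[di == d]]))
    }
    out[[k]] <- new_count_series(parts[1], as.integer(parts[2]), days, raw,
                                 users)
  }
  out[order(names(out))]
}

#' Normalise a count series for the weekly activity pattern
#'
#' Divides each day's raw count by a trailing weekday factor
#' `f(w) = mean(count | weekday w, window) / mean(count, window)` computed
#' over the `history_window_days` days preceding the day (truncated to the
#' available history). Factors are floored at 0.1; days with fewer than 14
#' days of history keep their raw count (`f = 1`), as does any day whose
#' trailing window is all zero.
#'
#' @param series a `count_series`.
#' @param history_window_days trailing window length, days (>= 14).
#' @return the series with its `normalised` component replaced.
#' @export
weekday_normalise <- function(series, history_window_days = 56) {
  stopifnot(inherits(series, "count_series"), history_window_days >= 14)
  n <- length(series$days)
  wd <- as.POSIXlt(series$days)$wday
  norm <- as.numeric(series$raw)
  for (i in seq_len(n)) {
    lo <- max(1L, i - as.integer(history_window_days))
    hist <- lo:(i - 1L)
    if (i == 1L || length(hist) < 14L) next
    overall <- mean(series$raw[hist])
    if (overall <= 0) next
    same_wd <- hist[wd[hist] == wd[i]]
    if (length(same_wd) == 0) next
    f <- mean(series$raw[same_wd]) / overall
    f <- max(f, 0.1)
    norm[i] <- series$raw[i] / f
  }
  series$normalised <- norm
  series
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("Count series '%s' in cluster %d: %d days (%s .. %s), %d tweets\n",
              x$group_id, x$cluster_id, length(x$days),
              format(x$days[1]), format(x$days[length(x$days)]),
              sum(x$raw)))
  invisible(x)
}

#' Export a count series as a TSV-ready data.frame
#'
#' @param x a `count_series`.
#' @param ... unused.
#' @return data.frame with columns date, raw, normalised, users.
#' @export
as.data.frame.count_series <- function(x, ...) {
  data.frame(date = x$days, raw = x$raw, normalised = x$normalised,
             users = x$users, stringsAsFactors = FALSE)
}
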