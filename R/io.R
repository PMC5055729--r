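# Reading and writing the pipeline's file formats: JSON Lines tweet streams
# (internal and public-API dialects), JSON Lines news corpora, JSON cluster
# models, and the TSV event report.

empty_tweets <- function() {
  data.frame(
    id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
    user_id = character(), lat = numeric(), lon = numeric(),
    text = character(), is_retweet = logical(),
    stringsAsFactors = FALSE
  )
}

parse_iso_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"),
                    optional = TRUE)
  out
}

parse_api_time <- function(x) {
  old <- Sys.getlocale("LC_TIME")
  on.exit(Sys.setlocale("LC_TIME", old), add = TRUE)
  Sys.setlocale("LC_TIME", "C")
  strptime(x, format = "%a %b %d %H:%M:%S %z %Y", tz = "UTC")
}

tweet_from_json <- function(rec) {
  if (!is.list(rec)) return(NULL)
  if (!is.null(rec$id_str) || !is.null(rec$created_at)) {
    # public streaming-API dialect; coordinates are GeoJSON [lon, lat]
    coords <- rec$coordinates$coordinates
    if (is.null(coords) || length(coords) < 2 ||
        !all(is.finite(as.numeric(coords[1:2])))) {
      return("nocoord")
    }
    ts <- parse_api_time(rec$created_at)
    if (is.na(ts)) return(NULL)
    list(id = as.character(rec$id_str),
         timestamp = as.POSIXct(ts, tz = "UTC"),
         user_id = as.character(rec$user$id_str),
         lat = as.numeric(coords[[2]]), lon = as.numeric(coords[[1]]),
         text = as.character(rec$text),
         is_retweet = !is.null(rec$retweeted_status))
  } else {
    need <- c("id", "timestamp", "user_id", "text")
    if (!all(need %in% names(rec))) return(NULL)
    if (is.null(rec$lat) || is.null(rec$lon) ||
        !is.finite(as.numeric(rec$lat)) || !is.finite(as.numeric(rec$lon))) {
      return("nocoord")
    }
    ts <- parse_iso_time(rec$timestamp)
    if (is.na(ts)) return(NULL)
    list(id = as.character(rec$id), timestamp = ts,
         user_id = as.character(rec$user_id),
         lat = as.numeric(rec$lat), lon = as.numeric(rec$lon),
         text = as.character(rec$text),
         is_retweet = isTRUE(rec$is_retweet))
  }
}

#' Read a JSON Lines tweet stream
#'
#' Accepts both the package's flat internal schema (`id`, `timestamp`,
#' `user_id`, `lat`, `lon`, `text`, `is_retweet`) and the public streaming-API
#' schema (`id_str`, `created_at`, `user.id_str`, GeoJSON
#' `coordinates.coordinates` as `[lon, lat]`, `text`, `retweeted_status`),
#' detected per line. Malformed lines, lines without coordinates, invalid
#' coordinates, empty texts and duplicate ids are skipped and counted in a
#' message summary; the returned tweets are sorted by timestamp.
#'
#' @param path path to a JSON Lines file.
#' @param drop_retweets drop tweets flagged as retweets.
#' @param quiet suppress the skip-count message.
#' @return data.frame of tweets sorted by `timestamp`.
#' @export
read_tweets <- function(path, drop_retweets = TRUE, quiet = FALSE) {
  if (!file.exists(path)) stop("tweet file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  skipped_malformed <- 0L
  skipped_nocoord <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    parsed <- if (is.null(rec)) NULL else tweet_from_json(rec)
    if (is.null(parsed)) {
      skipped_malformed <- skipped_malformed + 1L
    } else if (identical(parsed, "nocoord")) {
      skipped_nocoord <- skipped_nocoord + 1L
    } else {
      recs[[i]] <- parsed
    }
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0) {
    tw <- empty_tweets()
  } else {
    tw <- data.frame(
      id = vapply(recs, `[[`, "", "id"),
      timestamp = as.POSIXct(vapply(recs, function(r)
        as.numeric(r$timestamp), 0), tz = "UTC", origin = "1970-01-01"),
      user_id = vapply(recs, `[[`, "", "user_id"),
      lat = vapply(recs, `[[`, 0, "lat"),
      lon = vapply(recs, `[[`, 0, "lon"),
      text = vapply(recs, `[[`, "", "text"),
      is_retweet = vapply(recs, `[[`, TRUE, "is_retweet"),
      stringsAsFactors = FALSE
    )
  }
  bad_range <- tw$lat < -90 | tw$lat > 90 | tw$lon < -180 | tw$lon > 180 |
    !nzchar(tw$text)
  skipped_invalid <- sum(bad_range)
  tw <- tw[!bad_range, , drop = FALSE]
  dup <- duplicated(tw$id)
  skipped_dup <- sum(dup)
  tw <- tw[!dup, , drop = FALSE]
  if (drop_retweets) tw <- tw[!tw$is_retweet, , drop = FALSE]
  tw <- tw[order(tw$timestamp), , drop = FALSE]
  rownames(tw) <- NULL
  if (!quiet && (skipped_malformed + skipped_nocoord + skipped_invalid +
                 skipped_dup) > 0) {
    message(sprintf(
      "read_tweets: kept %d tweets; skipped %d malformed, %d without coordinates, %d invalid, %d duplicate ids",
      nrow(tw), skipped_malformed, skipped_nocoord, skipped_invalid,
      skipped_dup))
  }
  attr(tw, "skipped") <- c(malformed = skipped_malformed,
                           nocoord = skipped_nocoord,
                           invalid = skipped_invalid,
                           duplicate = skipped_dup)
  tw
}

#' Write tweets as JSON Lines (internal dialect)
#'
#' @param tweets tweet data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    rec <- list(
      id = tweets$id[i],
      timestamp = format(tweets$timestamp[i], "%Y-%m-%dT%H:%M:%SZ",
                         tz = "UTC"),
      user_id = tweets$user_id[i],
      lat = tweets$lat[i], lon = tweets$lon[i],
      text = tweets$text[i], is_retweet = tweets$is_retweet[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a JSON Lines news corpus
#'
#' One article per line with fields `title`, `body`, `date` (ISO date),
#' `source`, `url` and optionally `article_id` (generated from the line number
#' when absent). Records missing a title or a parseable date are skipped with
#' a warning count. Order is the file order.
#'
#' @param path path to the JSON Lines file.
#' @param quiet suppress the skip-count message.
#' @return data.frame of articles with a `Date`-typed `date` column.
#' @export
read_news_corpus <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("news file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  skipped <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    ok <- !is.null(rec) && !is.null(rec$title) && nzchar(rec$title) &&
      !is.null(rec$date) && !is.na(as.Date(as.character(rec$date),
                                           optional = TRUE))
    if (!ok) {
      skipped <- skipped + 1L
      next
    }
    recs[[i]] <- list(
      article_id = if (!is.null(rec$article_id))
        as.character(rec$article_id) else sprintf("a%06d", i),
      title = as.character(rec$title),
      body = if (is.null(rec$body)) "" else as.character(rec$body),
      date = as.Date(as.character(rec$date)),
      source = if (is.null(rec$source)) "" else as.character(rec$source),
      url = if (is.null(rec$url)) "" else as.character(rec$url)
    )
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0) {
    out <- data.frame(article_id = character(), title = character(),
                      body = character(), date = as.Date(character()),
                      source = character(), url = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      article_id = vapply(recs, `[[`, "", "article_id"),
      title = vapply(recs, `[[`, "", "title"),
      body = vapply(recs, `[[`, "", "body"),
      date = as.Date(vapply(recs, function(r) as.character(r$date), "")),
      source = vapply(recs, `[[`, "", "source"),
      url = vapply(recs, `[[`, "", "url"),
      stringsAsFactors = FALSE
    )
  }
  if (!quiet && skipped > 0) {
    message(sprintf("read_news_corpus: kept %d articles; skipped %d records",
                    nrow(out), skipped))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a news corpus as JSON Lines
#'
#' @param articles article data.frame (see [read_news_corpus()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_news_corpus <- function(articles, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(articles))) {
    rec <- list(article_id = articles$article_id[i],
                title = articles$title[i], body = articles$body[i],
                date = format(articles$date[i]), source = articles$source[i],
                url = articles$url[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write / read a cluster model as JSON
#'
#' @param model a `cluster_model` object (see [build_cluster_model()]).
#' @param path output path.
#' @return `path` (write) or the model (read).
#' @export
write_cluster_model <- function(model, path) {
  payload <- list(
    noise_id = model$noise_id,
    clusters = lapply(model$clusters, function(cl) {
      list(cluster_id = cl$cluster_id, label = cl$label,
           area_km2 = cl$area_km2,
           hull = lapply(seq_len(nrow(cl$hull)), function(i)
             c(cl$hull[i, "lat"], cl$hull[i, "lon"])))
    })
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  clusters <- lapply(payload$clusters, function(cl) {
    hull <- do.call(rbind, lapply(cl$hull, function(v) as.numeric(v)))
    colnames(hull) <- c("lat", "lon")
    list(cluster_id = as.integer(cl$cluster_id), label = as.character(cl$label),
         hull = hull, area_km2 = as.numeric(cl$area_km2))
  })
  structure(list(clusters = clusters,
                 noise_id = as.integer(payload$noise_id)),
            class = "cluster_model")
}

#' Write the TSV event report
#'
#' One row per alarm: id, keyword group, cluster, start and end dates, the
#' severity statistic mu_max, the tweet-user ratio and the event status.
#'
#' @param detection a `tnt_detection` object from [detect_events()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_report <- function(detection, path) {
  df <- as.data.frame(detection)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
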