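# Event detection: EARS C2/C3 aberration flags on daily count series,
# grouping of consecutive alarm days, the MAD-based severity statistic mu and
# its alarm-level maximum mu_max, the tweet-user spam ratio, and the final
# event classification.

#' EARS C2 alarm flags
#'
#' C2 uses a sliding baseline of `window` days (optionally separated from the
#' tested day by `gap_days`) and flags day t when the count exceeds the
#' baseline mean by more than `k_sigma` baseline standard deviations (sample
#' sd, floored at `sigma_floor`). Days without a full baseline are never
#' flagged.
#'
#' @param counts numeric vector of daily counts.
#' @param window baseline length, days.
#' @param k_sigma trigger multiplier.
#' @param sigma_floor lower bound on the baseline standard deviation.
#' @param gap_days guard band between baseline and tested day.
#' @return logical vector, same length as `counts`.
#' @export
c2_flags <- function(counts, window = 7, k_sigma = 3, sigma_floor = 0.5,
                     gap_days = 0) {
  n <- length(counts)
  flags <- logical(n)
  lead <- window + gap_days
  if (n <= lead) return(flags)
  for (t in (lead + 1L):n) {
    base <- counts[(t - lead):(t - gap_days - 1L)]
    s <- stats::sd(base)
    if (is.na(s)) s <- 0
    flags[t] <- (counts[t] - mean(base)) > k_sigma * max(s, sigma_floor)
  }
  flags
}

#' EARS C3 alarm flags
#'
#' In the default (`"paper"`) formulation C3 flags day t when at least
#' `min_alarms` C2 alarms occurred in the trailing `lookback` days (the tested
#' day included).
#'
#' @param c2 logical vector of C2 flags.
#' @param lookback trailing window, days (including the tested day).
#' @param min_alarms minimum number of C2 alarms in the window.
#' @return logical vector, same length as `c2`.
#' @export
c3_flags <- function(c2, lookback = 3, min_alarms = 2) {
  n <- length(c2)
  flags <- logical(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - as.integer(lookback) + 1L)
    flags[t] <- sum(c2[lo:t]) >= min_alarms
  }
  flags
}

# CDC-style C3: cumulative exceedance sum_{i=t-2..t} max(0, z_i - 1) > 2,
# with z the C2 standardised residual.
c3_flags_cdc <- function(counts, window = 7, k_sigma = 3, sigma_floor = 0.5,
                         gap_days = 0) {
  n <- length(counts)
  z <- rep(NA_real_, n)
  lead <- window + gap_days
  if (n > lead) {
    for (t in (lead + 1L):n) {
      base <- counts[(t - lead):(t - gap_days - 1L)]
      s <- stats::sd(base)
      if (is.na(s)) s <- 0
      z[t] <- (counts[t] - mean(base)) / max(s, sigma_floor)
    }
  }
  flags <- logical(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - 2L)
    zz <- z[lo:t]
    zz <- zz[!is.na(zz)]
    if (length(zz)) flags[t] <- sum(pmax(0, zz - 1)) > 2
  }
  flags
}

#' Group alarmed days into alarms
#'
#' A day is alarmed when C2 or C3 fires; maximal runs of consecutive alarmed
#' days form one alarm.
#'
#' @param c2,c3 logical flag vectors aligned to the series days.
#' @return data.frame with one row per alarm: `start_idx`, `end_idx`
#'   (positions in the series).
#' @export
group_alarms <- function(c2, c3) {
  alarmed <- c2 | c3
  r <- rle(alarmed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

#' MAD-based severity statistic
#'
#' `mu = (observation - median(history)) / max(MAD(history), mad_floor)`,
#' where the history is every count strictly before the observed day and MAD
#' is the (unscaled) median absolute deviation from the median. The floor
#' keeps the statistic defined on zero-dispersion histories.
#'
#' @param history numeric vector of prior counts (non-empty).
#' @param observation the count at the evaluated day.
#' @param mad_floor lower bound on the MAD.
#' @return numeric scalar.
#' @export
mu_statistic <- function(history, observation, mad_floor = 1) {
  if (length(history) == 0) stop("mu_statistic: empty history", call. = FALSE)
  med <- stats::median(history)
  mad <- stats::median(abs(history - med))
  (observation - med) / max(mad, mad_floor)
}

#' Alarm-level severity maximum
#'
#' The maximum of [mu_statistic()] over the alarm's days, each evaluated
#' against the full series history strictly before that day.
#'
#' @param counts numeric vector, the full series the alarm was raised on.
#' @param start_idx,end_idx alarm day positions in `counts`.
#' @param mad_floor lower bound on the MAD.
#' @return list with `mu` (per alarm day) and `mu_max`.
#' @export
alarm_mu <- function(counts, start_idx, end_idx, mad_floor = 1) {
  idx <- start_idx:end_idx
  mu <- vapply(idx, function(t) {
    if (t < 2L) return(NA_real_)
    mu_statistic(counts[seq_len(t - 1L)], counts[t], mad_floor)
  }, 0)
  list(mu = mu, mu_max = if (all(is.na(mu))) NA_real_ else max(mu,
                                                               na.rm = TRUE))
}

#' Tweet-user ratio of an alarm
#'
#' Tweets per distinct author among the alarm's gist tweets; values well above
#' 1 indicate a few accounts tweeting repeatedly (spam).
#'
#' @param tweets non-empty tweet data.frame.
#' @return numeric scalar >= 1.
#' @export
tweet_user_ratio <- function(tweets) {
  if (nrow(tweets) == 0) stop("tweet_user_ratio: empty tweet set",
                              call. = FALSE)
  nrow(tweets) / length(unique(tweets$user_id))
}

#' Classify alarms into events
#'
#' An alarm is an event iff `mu_max >= mu_max_threshold` and
#' `tweet_user_ratio <= tweet_user_ratio_threshold`. When both filters fail
#' the spam label takes precedence.
#'
#' @param mu_max numeric vector of alarm severities.
#' @param ratio numeric vector of tweet-user ratios.
#' @param config a [tnt_config()].
#' @return character vector: `"event"`, `"rejected_low_mu"` or
#'   `"rejected_spam"`.
#' @export
classify_events <- function(mu_max, ratio, config = tnt_config()) {
  config <- as_tnt_config(config)
  spam <- ratio > config$tweet_user_ratio_threshold
  low <- is.na(mu_max) | mu_max < config$mu_max_threshold
  ifelse(spam, "rejected_spam", ifelse(low, "rejected_low_mu", "event"))
}

#' Precision / recall / F1 at a severity threshold
#'
#' "At or above" semantics: instances with `mu_max >= threshold` are
#' positives. Precision is defined as 1 when no instance is at or above the
#' threshold; F1 is 0 when precision + recall is 0.
#'
#' @param mu_max numeric vector of alarm severities.
#' @param verified logical vector, external verification per alarm.
#' @param threshold severity threshold.
#' @return named list with `precision`, `recall`, `f1` and the confusion
#'   counts.
#' @export
threshold_metrics <- function(mu_max, verified, threshold) {
  stopifnot(length(mu_max) == length(verified), length(mu_max) > 0)
  pos <- mu_max >= threshold
  tp <- sum(pos & verified)
  fp <- sum(pos & !verified)
  fn <- sum(!pos & verified)
  tn <- sum(!pos & !verified)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Threshold sweep over a labelled alarm set
#'
#' @param mu_max,verified labelled alarms as in [threshold_metrics()].
#' @param thresholds numeric vector of thresholds to evaluate.
#' @return data.frame with one row per threshold.
#' @export
threshold_sweep <- function(mu_max, verified, thresholds = 0:20) {
  rows <- lapply(thresholds, function(th) {
    m <- threshold_metrics(mu_max, verified, th)
    data.frame(threshold = th, precision = m$precision, recall = m$recall,
               f1 = m$f1, tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
  })
  do.call(rbind, rows)
}

area_codes <- function(labels) {
  code <- toupper(substr(labels, 1, 1))
  dup <- code %in% code[duplicated(code)]
  code[dup] <- toupper(substr(labels[dup], 1, 2))
  code
}

filter_gist <- function(tweets, cluster, matched, group_id, cluster_id,
                        from, to) {
  day <- utc_date(tweets$timestamp)
  keep <- cluster == cluster_id & day >= from & day <= to &
    vapply(matched, function(g) group_id %in% g, TRUE)
  out <- tweets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect events in a geo-tagged tweet stream
#'
#' Runs the full detection stage: matches tweets to keyword groups, assigns
#' them to cluster areas, aggregates daily count series, normalises for the
#' weekly pattern, raises EARS C2/C3 alarms, groups consecutive alarm days,
#' computes the severity statistic mu_max and the tweet-user ratio per alarm,
#' and classifies each alarm as an event or a rejection.
#'
#' @param tweets tweet data.frame (see [read_tweets()]).
#' @param model a `cluster_model`.
#' @param groups keyword groups from [read_keyword_groups()].
#' @param config a [tnt_config()] (or a list of overrides).
#' @param date_range optional length-2 `Date` vector; defaults to the tweet
#'   date span.
#' @param noise_filter optional `noise_filter` applied to the tweets before
#'   aggregation (train one per event class; pass pre-filtered tweets for
#'   finer control).
#' @param sentiment_scorer optional function mapping a character vector of
#'   texts to numeric sentiment scores; tweets with extreme scores join the
#'   `"very positive"` / `"very negative"` pseudo-groups (see
#'   [add_sentiment_groups()]).
#' @return an object of class `tnt_detection` with components `alarms` (list
#'   of alarm records), `decisions` (data.frame), `series` (the normalised
#'   count series) and `config`.
#' @export
detect_events <- function(tweets, model, groups, config = tnt_config(),
                          date_range = NULL, noise_filter = NULL,
                          sentiment_scorer = NULL) {
  config <- as_tnt_config(config)
  tweets <- apply_noise_filter(tweets, noise_filter)
  cluster <- assign_cluster(cbind(tweets$lat, tweets$lon), model)
  matched <- match_groups(tweets$text, groups)
  if (!is.null(sentiment_scorer)) {
    matched <- add_sentiment_groups(matched, sentiment_scorer(tweets$text))
  }
  attr(tweets, "cluster") <- cluster
  attr(tweets, "matched") <- matched
  series <- aggregate_counts(tweets, model, groups, date_range)
  series <- lapply(series, weekday_normalise,
                   history_window_days = config$weekday_window_days)
  labels <- stats::setNames(
    vapply(model$clusters, `[[`, "", "label"),
    vapply(model$clusters, `[[`, 0L, "cluster_id"))
  codes <- stats::setNames(area_codes(labels), names(labels))

  alarms <- list()
  used_ids <- character()
  for (s in series) {
    x <- s$normalised
    c2 <- c2_flags(x, config$c2_window_days, config$c2_sigma_multiplier,
                   config$c2_sigma_floor, config$c2_gap_days)
    c3 <- if (config$c3_mode == "cdc") {
      c3_flags_cdc(x, config$c2_window_days, config$c2_sigma_multiplier,
                   config$c2_sigma_floor, config$c2_gap_days)
    } else {
      c3_flags(c2, config$c3_lookback_days, config$c3_min_alarms)
    }
    runs <- group_alarms(c2, c3)
    for (r in seq_len(nrow(runs))) {
      si <- runs$start_idx[r]
      ei <- runs$end_idx[r]
      sev <- alarm_mu(x, si, ei, config$mad_floor)
      gist <- filter_gist(tweets, cluster, matched, s$group_id, s$cluster_id,
                          s$days[si], s$days[ei])
      if (nrow(gist) == 0) next  # normalisation artefact, no actual tweets
      ratio <- tweet_user_ratio(gist)
      base_id <- sprintf("%s%s-%s",
                         toupper(substr(gsub(" ", "", s$group_id), 1, 2)),
                         codes[[as.character(s$cluster_id)]],
                         format(s$days[si], "%d-%m"))
      alarm_id <- base_id
      k <- 1L
      while (alarm_id %in% used_ids) {
        k <- k + 1L
        alarm_id <- paste0(base_id, "-", k)
      }
      used_ids <- c(used_ids, alarm_id)
      alarms[[length(alarms) + 1L]] <- list(
        alarm_id = alarm_id, group_id = s$group_id,
        cluster_id = s$cluster_id,
        start_date = s$days[si], end_date = s$days[ei],
        day_records = data.frame(
          date = s$days[si:ei], count = x[si:ei],
          c2_triggered = c2[si:ei], c3_triggered = c3[si:ei],
          mu = sev$mu),
        mu_max = sev$mu_max,
        tweet_count = nrow(gist),
        distinct_user_count = length(unique(gist$user_id)),
        tweet_user_ratio = ratio)
    }
  }

  mu_max <- vapply(alarms, `[[`, 0, "mu_max")
  ratio <- vapply(alarms, `[[`, 0, "tweet_user_ratio")
  status <- if (length(alarms)) classify_events(mu_max, ratio, config)
  else character()
  decisions <- data.frame(
    alarm_id = vapply(alarms, `[[`, "", "alarm_id"),
    status = status,
    mu_threshold_used = rep(config$mu_max_threshold, length(alarms)),
    ratio_threshold_used = rep(config$tweet_user_ratio_threshold,
                               length(alarms)),
    stringsAsFactors = FALSE)

  structure(list(alarms = alarms, decisions = decisions, series = series,
                 config = config),
            class = "tnt_detection")
}

#' @export
as.data.frame.tnt_detection <- function(x, ...) {
  if (length(x$alarms) == 0) {
    return(data.frame(alarm_id = character(), group = character(),
                      cluster = integer(), start = as.Date(character()),
                      end = as.Date(character()), mu_max = numeric(),
                      tweet_user_ratio = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    alarm_id = vapply(x$alarms, `[[`, "", "alarm_id"),
    group = vapply(x$alarms, `[[`, "", "group_id"),
    cluster = vapply(x$alarms, `[[`, 0L, "cluster_id"),
    start = as.Date(vapply(x$alarms, function(a) format(a$start_date), "")),
    end = as.Date(vapply(x$alarms, function(a) format(a$end_date), "")),
    mu_max = vapply(x$alarms, `[[`, 0, "mu_max"),
    tweet_user_ratio = vapply(x$alarms, `[[`, 0, "tweet_user_ratio"),
    status = x$decisions$status,
    stringsAsFactors = FALSE)
}

#' @export
print.tnt_detection <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Event detection over %d count series: %d alarms, %d events\n",
              length(x$series), nrow(df), sum(df$status == "event")))
  if (nrow(df)) print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tnt_detection <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Alarms: %d (events %d, low-severity %d, spam %d)\n",
              nrow(df), sum(df$status == "event"),
              sum(df$status == "rejected_low_mu"),
              sum(df$status == "rejected_spam")))
  if (nrow(df)) {
    cat(sprintf("mu_max range: %.2f .. %.2f; ratio range: %.2f .. %.2f\n",
                min(df$mu_max, na.rm = TRUE), max(df$mu_max, na.rm = TRUE),
                min(df$tweet_user_ratio), max(df$tweet_user_ratio)))
  }
  invisible(df)
}

#' Plot a detection result
#'
#' One panel per count series: normalised daily counts with alarm days marked
#' and event alarms shaded.
#'
#' @param x a `tnt_detection`.
#' @param keys series keys to plot (default: all series with alarms, up to 4).
#' @param ... passed to [graphics::plot()].
#' @export
plot.tnt_detection <- function(x, keys = NULL, ...) {
  df <- as.data.frame(x)
  if (is.null(keys)) {
    with_alarms <- unique(paste(df$group, df$cluster, sep = "|"))
    keys <- utils::head(if (length(with_alarms)) with_alarms
                        else names(x$series), 4)
  }
  old <- graphics::par(mfrow = c(length(keys), 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in keys) {
    s <- x$series[[k]]
    if (is.null(s)) next
    graphics::plot(s$days, s$normalised, type = "l",
                   xlab = "", ylab = "normalised count", main = k, ...)
    for (a in x$alarms) {
      if (paste(a$group_id, a$cluster_id, sep = "|") != k) next
      graphics::rect(as.numeric(a$start_date) - 0.5, 0,
                     as.numeric(a$end_date) + 0.5, max(s$normalised),
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  invisible(x)
}
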