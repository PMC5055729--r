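#' Run configuration
#'
#' Builds the configuration object consumed by the detection and summarisation
#' stages. Defaults follow the recommended operating point of the method:
#' EARS C2 with a sliding 7-day baseline and a 3-sigma trigger, C3 requiring
#' at least 2 C2 alarms over the trailing 3 days, an event severity threshold
#' of `mu_max >= 4`, a spam tweet-user ratio cut-off of 1.5, a 28-day
#' summarisation baseline, a 30-tweet minimum gist, Fisher alpha 0.05 with the
#' top two unigrams and top two bigrams, 10 news articles per search term, and
#' a PCSS coherence/relatedness threshold of -0.08.
#'
#' @param c2_window_days length of the sliding C2 baseline, days.
#' @param c2_sigma_multiplier number of baseline standard deviations a count
#'   must exceed the baseline mean by to trigger C2.
#' @param c2_sigma_floor lower bound on the baseline standard deviation, to
#'   keep the trigger defined on zero-variance baselines.
#' @param c2_gap_days guard band between the baseline and the tested day.
#'   The default 2 is the standard EARS C2 placement (baseline days t-9..t-3),
#'   which keeps the first day of a burst out of the second day's baseline so
#'   multi-day bursts produce multi-day alarms; 0 uses the 7 days immediately
#'   preceding.
#' @param c3_lookback_days trailing window (including the tested day) over
#'   which C2 alarms are accumulated for C3.
#' @param c3_min_alarms minimum number of C2 alarms in the lookback window for
#'   C3 to trigger.
#' @param mu_max_threshold minimum alarm severity (MADs above the series
#'   median) for an alarm to be classified as an event.
#' @param tweet_user_ratio_threshold maximum tweets-per-distinct-user ratio;
#'   alarms above it are rejected as spam.
#' @param mad_floor lower bound on the median absolute deviation in the
#'   severity statistic.
#' @param baseline_days length of the summarisation baseline before the event.
#' @param min_event_tweets minimum gist size for an event to be summarisable.
#' @param ngram_doc_fraction minimum fraction of gist tweets an n-gram must
#'   occur in to become a candidate term.
#' @param fisher_alpha significance level for the one-sided Fisher test.
#' @param top_k_unigrams,top_k_bigrams number of most significant unigrams and
#'   bigrams kept as search terms.
#' @param news_per_term number of news articles retrieved per search term.
#' @param pcss_threshold minimum body PCSS for a term's article set to count
#'   as coherent.
#' @param relatedness_threshold minimum cross-set title PCSS for two terms to
#'   count as related. Must be positive to be discriminative: two sets with
#'   fully disjoint vocabulary have a cross-PCSS of exactly 0, so a negative
#'   threshold could never drop an unrelated term.
#' @param top_k_articles,top_k_tweets lengths of the ranked article and tweet
#'   lists in an event summary.
#' @param dbscan_eps_km DBSCAN neighbourhood radius in kilometres
#'   (great-circle distance).
#' @param dbscan_min_points DBSCAN core-point density threshold.
#' @param stopword_top_n number of most frequent corpus tokens added to the
#'   standard stopword list.
#' @param weekday_window_days trailing window for the weekday normalisation
#'   factors, days.
#' @param c3_mode `"paper"` counts C2 binary alarms in the lookback window;
#'   `"cdc"` accumulates the CDC C3 cumulative exceedance statistic.
#'
#' @return a list of class `tnt_config`.
#' @export
tnt_config <- function(c2_window_days = 7,
                       c2_sigma_multiplier = 3,
                       c2_sigma_floor = 0.5,
                       c2_gap_days = 2,
                       c3_lookback_days = 3,
                       c3_min_alarms = 2,
                       mu_max_threshold = 4,
                       tweet_user_ratio_threshold = 1.5,
                       mad_floor = 1,
                       baseline_days = 28,
                       min_event_tweets = 30,
                       ngram_doc_fraction = 0.05,
                       fisher_alpha = 0.05,
                       top_k_unigrams = 2,
                       top_k_bigrams = 2,
                       news_per_term = 10,
                       pcss_threshold = -0.08,
                       relatedness_threshold = 0.05,
                       top_k_articles = 5,
                       top_k_tweets = 5,
                       dbscan_eps_km = 10,
                       dbscan_min_points = 10,
                       stopword_top_n = 200,
                       weekday_window_days = 56,
                       c3_mode = c("paper", "cdc")) {
  c3_mode <- match.arg(c3_mode)
  cfg <- list(
    c2_window_days = as.integer(c2_window_days),
    c2_sigma_multiplier = as.numeric(c2_sigma_multiplier),
    c2_sigma_floor = as.numeric(c2_sigma_floor),
    c2_gap_days = as.integer(c2_gap_days),
    c3_lookback_days = as.integer(c3_lookback_days),
    c3_min_alarms = as.integer(c3_min_alarms),
    mu_max_threshold = as.numeric(mu_max_threshold),
    tweet_user_ratio_threshold = as.numeric(tweet_user_ratio_threshold),
    mad_floor = as.numeric(mad_floor),
    baseline_days = as.integer(baseline_days),
    min_event_tweets = as.integer(min_event_tweets),
    ngram_doc_fraction = as.numeric(ngram_doc_fraction),
    fisher_alpha = as.numeric(fisher_alpha),
    top_k_unigrams = as.integer(top_k_unigrams),
    top_k_bigrams = as.integer(top_k_bigrams),
    news_per_term = as.integer(news_per_term),
    pcss_threshold = as.numeric(pcss_threshold),
    relatedness_threshold = as.numeric(relatedness_threshold),
    top_k_articles = as.integer(top_k_articles),
    top_k_tweets = as.integer(top_k_tweets),
    dbscan_eps_km = as.numeric(dbscan_eps_km),
    dbscan_min_points = as.integer(dbscan_min_points),
    stopword_top_n = as.integer(stopword_top_n),
    weekday_window_days = as.integer(weekday_window_days),
    c3_mode = c3_mode
  )
  positive <- c(
    "c2_window_days", "c2_sigma_multiplier", "c3_lookback_days",
    "c3_min_alarms", "baseline_days", "min_event_tweets", "news_per_term",
    "top_k_articles", "top_k_tweets", "dbscan_eps_km", "dbscan_min_points",
    "weekday_window_days"
  )
  for (p in positive) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0) {
      stop(sprintf("config parameter '%s' must be positive", p), call. = FALSE)
    }
  }
  non_negative <- c("c2_sigma_floor", "c2_gap_days", "mad_floor",
                    "stopword_top_n", "top_k_unigrams", "top_k_bigrams")
  for (p in non_negative) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] < 0) {
      stop(sprintf("config parameter '%s' must be non-negative", p),
           call. = FALSE)
    }
  }
  for (p in c("ngram_doc_fraction", "fisher_alpha")) {
    if (!is.finite(cfg[[p]]) || cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      stop(sprintf("config parameter '%s' must lie in (0, 1)", p),
           call. = FALSE)
    }
  }
  class(cfg) <- "tnt_config"
  cfg
}

#' @export
print.tnt_config <- function(x, ...) {
  cat("Event detection / summarisation configuration\n")
  cat(sprintf("  C2: window %d d (gap %d d), trigger %.1f sigma (floor %.2f)\n",
              x$c2_window_days, x$c2_gap_days, x$c2_sigma_multiplier,
              x$c2_sigma_floor))
  cat(sprintf("  C3: >= %d C2 alarms in %d d (mode %s)\n",
              x$c3_min_alarms, x$c3_lookback_days, x$c3_mode))
  cat(sprintf("  event filters: mu_max >= %g, tweet-user ratio <= %g\n",
              x$mu_max_threshold, x$tweet_user_ratio_threshold))
  cat(sprintf("  summarisation: %d d baseline, >= %d gist tweets, alpha %g\n",
              x$baseline_days, x$min_event_tweets, x$fisher_alpha))
  cat(sprintf("  news: %d per term, PCSS >= %g, relatedness >= %g\n",
              x$news_per_term, x$pcss_threshold, x$relatedness_threshold))
  invisible(x)
}

as_tnt_config <- function(config) {
  if (inherits(config, "tnt_config")) return(config)
  if (is.null(config)) return(tnt_config())
  if (is.list(config)) return(do.call(tnt_config, config))
  stop("config must be NULL, a list, or a tnt_config object", call. = FALSE)
}
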