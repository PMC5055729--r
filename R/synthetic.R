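# Seeded synthetic fixtures: a geo-tagged tweet stream with per-(city, group)
# daily Poisson baselines, a weekly activity pattern, injected event bursts
# carrying planted vocabulary, spam users, and a matched news corpus with
# coherent distractor topics. Everything is deterministic given the scenario
# seed, and the generator records ground truth for property tests.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Synthetic scenario configuration
#'
#' Defines the study conditions the generator emulates: city centres with
#' Gaussian tweet scatter, per-(city, group) daily Poisson baselines with a
#' weekly activity pattern (weekends about 20 % busier), injected event
#' bursts with planted vocabulary, single-author spam bursts, and a matched
#' news corpus with coherent distractor topics.
#'
#' @param seed integer seed; the whole scenario is deterministic given it.
#' @param cities list of city specs (`name`, `centre` = c(lat, lon),
#'   `spread_km`, `in_cluster_fraction`).
#' @param group_ids primary keywords of the groups in play (must exist in
#'   `groups`).
#' @param groups keyword groups the texts draw their aliases from.
#' @param baseline_lambda mean daily tweet count per (city, group).
#' @param weekday_multipliers length-7 multipliers indexed Sunday..Saturday.
#' @param date_range length-2 `Date` vector.
#' @param events list of event specs (`city`, `group_id`, `dates` =
#'   c(start, end), `burst_multiplier`, `planted_vocabulary`,
#'   `n_news_articles`).
#' @param spam list of spam specs (`city`, `group_id`, `date`, `n_tweets`).
#' @param n_distractor_articles distractor news articles spread over the
#'   date range, in coherent off-topic groups.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            cities = list(
                              list(name = "Avonford",
                                   centre = c(52.0, -1.5),
                                   spread_km = 6,
                                   in_cluster_fraction = 0.85),
                              list(name = "Brynmouth",
                                   centre = c(53.4, -2.2),
                                   spread_km = 6,
                                   in_cluster_fraction = 0.85)),
                            group_ids = c("asthma", "vomit", "sadness"),
                            groups = read_keyword_groups(),
                            baseline_lambda = 5,
                            weekday_multipliers = c(1.15, 0.95, 0.95, 0.95,
                                                    0.95, 1.0, 1.2),
                            date_range = as.Date(c("2014-03-01",
                                                   "2014-05-09")),
                            events = list(list(
                              city = "Avonford", group_id = "asthma",
                              dates = as.Date(c("2014-05-06", "2014-05-07")),
                              burst_multiplier = 6,
                              planted_vocabulary = c("smog", "pollution",
                                                     "air pollution",
                                                     "saharan dust"),
                              n_news_articles = 5)),
                            spam = list(list(
                              city = "Brynmouth", group_id = "vomit",
                              date = as.Date("2014-05-06"), n_tweets = 20)),
                            n_distractor_articles = 12) {
  stopifnot(baseline_lambda > 0, all(weekday_multipliers > 0),
            length(weekday_multipliers) == 7, length(date_range) == 2,
            date_range[1] <= date_range[2])
  if (!all(group_ids %in% names(groups))) {
    stop("unknown group_ids in scenario", call. = FALSE)
  }
  city_names <- vapply(cities, `[[`, "", "name")
  for (ev in events) {
    stopifnot(ev$city %in% city_names, ev$group_id %in% group_ids,
              ev$burst_multiplier >= 1, length(ev$planted_vocabulary) >= 1,
              ev$dates[1] >= date_range[1], ev$dates[2] <= date_range[2])
  }
  for (sp in spam) {
    stopifnot(sp$city %in% city_names, sp$group_id %in% group_ids,
              sp$date >= date_range[1], sp$date <= date_range[2])
  }
  structure(list(seed = as.integer(seed), cities = cities,
                 group_ids = group_ids, groups = groups[group_ids],
                 baseline_lambda = baseline_lambda,
                 weekday_multipliers = weekday_multipliers,
                 date_range = as.Date(date_range), events = events,
                 spam = spam,
                 n_distractor_articles = as.integer(n_distractor_articles)),
            class = "scenario_config")
}

# Zipf-weighted filler vocabulary: a 230-word "common" pool whose head is
# frequent enough that the corpus-derived top-200 stopword cut lands inside
# it, plus a large rare tail.
filler_pools <- function() {
  list(common = sprintf("word%03d", 1:230),
       common_prob = (1:230)^-0.6,
       rare = sprintf("rare%04d", 1:2000))
}

synth_text <- function(group, planted_term = NULL, pools) {
  phrase <- sample(c(group$primary, group$aliases), 1)
  toks <- c(sample(pools$common, 6, replace = TRUE, prob = pools$common_prob),
            sample(pools$rare, 1))
  pieces <- append(toks, phrase, after = sample(0:length(toks), 1))
  if (!is.null(planted_term)) {
    pieces <- append(pieces, planted_term,
                     after = sample(0:length(pieces), 1))
  }
  paste(pieces, collapse = " ")
}

city_point <- function(city) {
  lat_sd <- city$spread_km / 110.574
  lon_sd <- city$spread_km / (111.320 * cos(city$centre[1] * pi / 180))
  c(city$centre[1] + stats::rnorm(1, 0, lat_sd),
    city$centre[2] + stats::rnorm(1, 0, lon_sd))
}

background_point <- function(cities) {
  lat0 <- mean(vapply(cities, function(ct) ct$centre[1], 0))
  lon0 <- mean(vapply(cities, function(ct) ct$centre[2], 0))
  c(stats::runif(1, lat0 - 2.5, lat0 + 2.5),
    stats::runif(1, lon0 - 3.5, lon0 + 3.5))
}

#' Generate a synthetic tweet stream
#'
#' For each (city, group, day) the tweet count is Poisson with mean
#' `baseline_lambda * weekday_multiplier`, multiplied by the burst factor of
#' any event covering that cell. Every tweet gets a coordinate (Gaussian
#' around the city centre with probability `in_cluster_fraction`, otherwise a
#' far background point), a timestamp uniform within the day, a fresh user id
#' and a templated text containing one group phrase; tweets in a burst cell
#' additionally carry one planted vocabulary term with probability 0.8. Spam
#' specs emit `n_tweets` near-identical tweets from a single user.
#'
#' @param config a [scenario_config()].
#' @return list with `tweets` (a tweet data.frame sorted by timestamp) and
#'   `truth` (realised per-day event counts, spam user ids, per-tweet
#'   in-cluster flags and planted-term flags).
#' @export
generate_stream <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  pools <- filler_pools()
  days <- seq(config$date_range[1], config$date_range[2], by = "day")
  wd <- as.POSIXlt(days)$wday + 1L  # 1 = Sunday
  with_seed(config$seed, {
    rows <- list()
    truth_counts <- list()
    tweet_no <- 0L
    user_no <- 0L
    in_cluster <- logical()
    planted_flag <- logical()
    for (city in config$cities) {
      for (gid in config$group_ids) {
        group <- config$groups[[gid]]
        ev <- NULL
        for (e in config$events) {
          if (e$city == city$name && e$group_id == gid) ev <- e
        }
        for (d in seq_along(days)) {
          mult <- 1
          bursting <- !is.null(ev) && days[d] >= ev$dates[1] &&
            days[d] <= ev$dates[2]
          if (bursting) mult <- ev$burst_multiplier
          lambda <- config$baseline_lambda *
            config$weekday_multipliers[wd[d]] * mult
          n <- stats::rpois(1, lambda)
          if (bursting) {
            truth_counts[[length(truth_counts) + 1L]] <- data.frame(
              city = city$name, group_id = gid, date = days[d], count = n,
              stringsAsFactors = FALSE)
          }
          if (n == 0) next
          for (k in seq_len(n)) {
            tweet_no <- tweet_no + 1L
            user_no <- user_no + 1L
            inside <- stats::runif(1) < city$in_cluster_fraction
            pt <- if (inside) city_point(city) else
              background_point(config$cities)
            planted <- if (bursting && stats::runif(1) < 0.8)
              sample(ev$planted_vocabulary, 1) else NULL
            rows[[tweet_no]] <- data.frame(
              id = sprintf("t%07d", tweet_no),
              timestamp = as.POSIXct(days[d], tz = "UTC") +
                stats::runif(1, 0, 86399),
              user_id = sprintf("u%07d", user_no),
              lat = pt[1], lon = pt[2],
              text = synth_text(group, planted, pools),
              is_retweet = FALSE, stringsAsFactors = FALSE)
            in_cluster <- c(in_cluster, inside)
            planted_flag <- c(planted_flag, !is.null(planted))
          }
        }
      }
    }
    spam_users <- character()
    for (sp in config$spam) {
      city <- config$cities[[match(sp$city,
                                   vapply(config$cities, `[[`, "", "name"))]]
      group <- config$groups[[sp$group_id]]
      spam_uid <- sprintf("spam%03d", length(spam_users) + 1L)
      spam_users <- c(spam_users, spam_uid)
      spam_text <- synth_text(group, NULL, pools)
      for (k in seq_len(sp$n_tweets)) {
        tweet_no <- tweet_no + 1L
        pt <- city_point(city)
        rows[[tweet_no]] <- data.frame(
          id = sprintf("t%07d", tweet_no),
          timestamp = as.POSIXct(sp$date, tz = "UTC") +
            stats::runif(1, 0, 86399),
          user_id = spam_uid, lat = pt[1], lon = pt[2],
          text = spam_text, is_retweet = FALSE, stringsAsFactors = FALSE)
        in_cluster <- c(in_cluster, TRUE)
        planted_flag <- c(planted_flag, FALSE)
      }
    }
    tweets <- do.call(rbind, rows)
    ord <- order(tweets$timestamp, tweets$id)
    tweets <- tweets[ord, , drop = FALSE]
    rownames(tweets) <- NULL
    truth <- list(
      events = config$events,
      event_counts = if (length(truth_counts)) do.call(rbind, truth_counts)
      else NULL,
      spam_user_ids = spam_users,
      in_cluster = in_cluster[ord],
      planted = planted_flag[ord],
      planted_article_ids = character())
    list(tweets = tweets, truth = truth)
  })
}

distractor_topics <- function() {
  list(
    football = c("football", "cup", "fixture", "striker", "transfer",
                 "goalkeeper", "midfield", "penalty", "derby", "manager",
                 "stadium", "supporters"),
    finance = c("shares", "market", "profits", "investors", "earnings",
                "dividend", "takeover", "shareholders", "forecast",
                "quarterly", "merger", "listing"),
    weatherfar = c("hurricane", "typhoon", "monsoon", "lightning",
                   "flooding", "evacuation", "storm", "landfall",
                   "forecasters", "coastal", "damage", "rainfall"))
}

#' Generate a matched synthetic news corpus
#'
#' Per event, `n_news_articles` articles dated within the event window (plus
#' one day, for next-day reporting) whose titles and bodies contain at least
#' two planted vocabulary terms plus shared topical filler; plus coherent
#' distractor articles in unrelated topic groups spread over the date range.
#' Planted article ids are recorded in the returned truth.
#'
#' @param config a [scenario_config()].
#' @param truth truth list from [generate_stream()].
#' @return list with `news` (article data.frame) and the updated `truth`.
#' @export
generate_news <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"))
  shared <- c("warning", "health", "levels", "officials", "residents",
              "reported")
  with_seed(config$seed + 1000L, {
    recs <- list()
    planted_ids <- character()
    for (ei in seq_along(config$events)) {
      ev <- config$events[[ei]]
      # story-specific detail vocabulary shared across this event's articles
      details <- sprintf("detail%d%02d", ei, 1:12)
      # headlines about one story share an anchor phrase (the story's name);
      # only the trailing editorial phrase varies
      anchor <- paste(utils::head(ev$planted_vocabulary, 2), collapse = " ")
      for (i in seq_len(ev$n_news_articles)) {
        id <- sprintf("ev%d_a%02d", ei, i)
        planted_ids <- c(planted_ids, id)
        terms <- sample(ev$planted_vocabulary,
                        min(3, max(2, length(ev$planted_vocabulary))))
        title <- paste(anchor, sample(c("health warning", "city alert"), 1))
        body <- paste(
          c(rep(terms, 3), shared, sample(details, 8, replace = TRUE),
            sample(filler_pools()$common, 4, replace = TRUE)),
          collapse = " ")
        recs[[length(recs) + 1L]] <- data.frame(
          article_id = id, title = title, body = body,
          date = sample(seq(ev$dates[1], ev$dates[2] + 1, by = "day"), 1),
          source = "synthetic-local-news", url = sprintf("local://%s", id),
          stringsAsFactors = FALSE)
      }
    }
    topics <- distractor_topics()
    all_days <- seq(config$date_range[1], config$date_range[2], by = "day")
    # the first distractor topic runs concurrently with the first event, so
    # unrelated-but-coherent news coexists with the event coverage
    concurrent_days <- if (length(config$events)) {
      ev1 <- config$events[[1]]
      seq(ev1$dates[1], ev1$dates[2] + 1, by = "day")
    } else {
      all_days
    }
    for (i in seq_len(config$n_distractor_articles)) {
      topic_no <- (i - 1L) %% length(topics) + 1L
      topic <- topics[[topic_no]]
      id <- sprintf("dis_a%02d", i)
      title <- paste(sample(topic, 3), collapse = " ")
      body <- paste(sample(topic, 8, replace = TRUE), collapse = " ")
      recs[[length(recs) + 1L]] <- data.frame(
        article_id = id, title = title, body = body,
        date = if (topic_no == 1L) sample(concurrent_days, 1) else
          sample(all_days, 1),
        source = "synthetic-local-news",
        url = sprintf("local://%s", id), stringsAsFactors = FALSE)
    }
    news <- do.call(rbind, recs)
    rownames(news) <- NULL
    truth$planted_article_ids <- planted_ids
    list(news = news, truth = truth)
  })
}
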