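# EARS C2/C3 flags, alarm grouping, the MAD severity statistic, the
# tweet-user ratio and event classification.

test_that("C2 triggers on the documented mean/sd arithmetic", {
  # flat series: difference is zero, never flags
  expect_false(any(c2_flags(rep(5, 8))))
  # baseline mean 10/7, sample sd sqrt(14)/7 ~ 0.5345 (above the 0.5 floor):
  # threshold is 10/7 + 3 * 0.5345 ~ 3.032
  base <- c(1, 2, 1, 2, 1, 2, 1)
  expect_true(c2_flags(c(base, 4))[8])
  expect_false(c2_flags(c(base, 3))[8])
  # all-zero baseline invokes the sigma floor: 2 > 1.5 > 1
  expect_true(c2_flags(c(rep(0, 7), 2), sigma_floor = 0.5)[8])
  expect_false(c2_flags(c(rep(0, 7), 1), sigma_floor = 0.5)[8])
  # days without a full baseline never flag
  expect_false(any(c2_flags(c(0, 0, 100))))
  # guard band shifts the baseline back
  x <- c(rep(5, 7), 50, 50, 50)
  expect_false(c2_flags(x)[10])          # contaminated baseline
  expect_true(c2_flags(x, gap_days = 2)[10])  # clean baseline
})

test_that("C3 counts C2 alarms in its trailing window", {
  expect_false(any(c3_flags(rep(FALSE, 10))))
  c2 <- rep(FALSE, 10)
  c2[c(4, 6)] <- TRUE   # t-2 and t
  expect_true(c3_flags(c2)[6])
  expect_false(c3_flags(c2)[8])
  single <- rep(FALSE, 10)
  single[5] <- TRUE
  expect_false(any(c3_flags(single)))
})

test_that("alarm grouping merges consecutive alarmed days and matches a run-length oracle", {
  c2 <- rep(FALSE, 10)
  c3 <- rep(FALSE, 10)
  c2[c(4, 5)] <- TRUE
  expect_equal(group_alarms(c2, c3), data.frame(start_idx = 4L, end_idx = 5L))
  c2[c(4, 5)] <- FALSE
  c2[c(4, 6)] <- TRUE
  runs <- group_alarms(c2, c3)
  expect_equal(nrow(runs), 2)
  set.seed(41)
  for (trial in 1:50) {
    a <- runif(30) < 0.3
    b <- runif(30) < 0.2
    expect_equal(group_alarms(a, b), oracle_runs(a | b),
                 ignore_attr = TRUE)
  }
})

test_that("mu is (observation - median) / floored MAD", {
  h <- c(1, 2, 2, 3, 3, 3, 4, 4, 9)   # median 3, MAD 1
  expect_equal(mu_statistic(h, 3), 0)
  expect_equal(mu_statistic(h, 9), 6)
  # even-length history: median of the two central values
  expect_equal(mu_statistic(c(1, 2, 3, 4), 5, mad_floor = 1), 2.5)
  # scale invariance while MAD stays above the floor
  expect_equal(mu_statistic(h * 10, 90), mu_statistic(h, 9))
  # strictly increasing in the observation
  mus <- vapply(5:15, function(o) mu_statistic(h, o), 0)
  expect_true(all(diff(mus) > 0))
  expect_error(mu_statistic(numeric(), 3), "empty history")
})

test_that("mu_max is the maximum per-day mu over the alarm days", {
  x <- c(rep(5, 20), 8, 30)
  one <- alarm_mu(x, 22, 22)
  expect_equal(one$mu_max, one$mu[1])
  both <- alarm_mu(x, 21, 22)
  expect_equal(both$mu_max, max(both$mu))
  expect_equal(both$mu_max, mu_statistic(x[1:21], 30))
  # a 10x burst scores strictly higher than a 3x burst on the same baseline
  base <- rep(5, 30)
  hi <- alarm_mu(c(base, 50), 31, 31)$mu_max
  lo <- alarm_mu(c(base, 15), 31, 31)$mu_max
  expect_gt(hi, lo)
})

test_that("tweet-user ratio and event classification follow the thresholds", {
  tw5 <- make_tweets(rep("flu", 5))
  expect_equal(tweet_user_ratio(tw5), 1)
  tw6 <- make_tweets(rep("flu", 6), users = rep(c("a", "b", "c"), 2))
  expect_equal(tweet_user_ratio(tw6), 2)
  expect_error(tweet_user_ratio(tw5[0, ]), "empty")

  cfg <- tnt_config()
  expect_equal(classify_events(20, 1.0, cfg), "event")
  expect_equal(classify_events(3.9, 1.0, cfg), "rejected_low_mu")
  expect_equal(classify_events(10, 1.6, cfg), "rejected_spam")
  # exactly at the thresholds: mu_max >= 4 passes, ratio must not exceed 1.5
  expect_equal(classify_events(4, 1.5, cfg), "event")
  # spam takes precedence when both filters fail
  expect_equal(classify_events(2, 3, cfg), "rejected_spam")
})

test_that("raising the severity threshold never adds events", {
  set.seed(42)
  mu <- runif(50, 0, 12)
  ratio <- 1 + rexp(50, 10)
  n_events <- vapply(seq(0, 12, by = 0.5), function(th) {
    sum(classify_events(mu, ratio, tnt_config(mu_max_threshold = th)) ==
          "event")
  }, 0)
  expect_true(all(diff(n_events) <= 0))
})

test_that("threshold metrics implement at-or-above semantics", {
  mu <- c(5, 4, 3, 1)
  verified <- c(TRUE, FALSE, TRUE, FALSE)
  m <- threshold_metrics(mu, verified, 4)
  expect_equal(m$tp, 1)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
  expect_equal(m$tn, 1)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  # recall is 1 at or below the minimum severity
  expect_equal(threshold_metrics(mu, verified, min(mu))$recall, 1)
  # no negatives: precision 1 at any threshold with TP > 0
  all_ver <- threshold_metrics(c(2, 5, 9), rep(TRUE, 3), 4)
  expect_equal(all_ver$precision, 1)
  # empty positive set: precision defined as 1
  expect_equal(threshold_metrics(mu, verified, 99)$precision, 1)
})

test_that("detect_events produces classified alarms with consistent records", {
  set.seed(43)
  model <- make_square_model(52, -1.5)
  groups <- make_groups(flu = character())
  days <- seq(as.Date("2014-03-01"), by = "day", length.out = 40)
  texts <- character(0); times <- as.POSIXct(character(), tz = "UTC")
  users <- character(0)
  for (d in seq_along(days)) {
    n <- if (d %in% 38:39) 25 else rpois(1, 4)
    if (n == 0) next
    texts <- c(texts, rep("flu today", n))
    times <- c(times, as.POSIXct(days[d], tz = "UTC") + seq_len(n))
    users <- c(users, sprintf("u%02d_%02d", d, seq_len(n)))
  }
  tw <- make_tweets(texts, times = times, users = users)
  det <- detect_events(tw, model, groups, tnt_config())
  df <- as.data.frame(det)
  expect_gt(nrow(df), 0)
  burst <- df[df$start <= days[39] & df$end >= days[38], ]
  expect_equal(nrow(burst), 1)
  expect_gte(burst$mu_max, 4)
  expect_equal(burst$status, "event")
  # alarm invariants
  for (a in det$alarms) {
    expect_true(a$start_date <= a$end_date)
    expect_equal(a$mu_max, max(a$day_records$mu, na.rm = TRUE))
    expect_gte(a$tweet_user_ratio, 1)
    expect_equal(as.numeric(diff(a$day_records$date)),
                 rep(1, nrow(a$day_records) - 1))
  }
})
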