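# Gist/baseline assembly, stopword construction, candidate n-grams and the
# one-sided Fisher exact enrichment test.

test_that("gist and baseline sets apply the documented filters", {
  model <- make_square_model(52, -1.5)
  groups <- make_groups(asthma = character(), flu = character())
  start <- as.Date("2014-04-02")
  mk <- function(day, text, lat = 52, lon = -1.5) {
    make_tweets(text, times = as.POSIXct(day, tz = "UTC") + 3600,
                lat = lat, lon = lon,
                ids = sprintf("x%05d", sample.int(1e5, 1)))
  }
  set.seed(51)
  tw <- rbind(
    mk(start, "asthma bad today"),
    mk(start + 1, "asthma again"),
    mk(start, "flu only in this one flu"),            # flu only
    mk(start, "asthma far away", lat = 40, lon = 10),  # outside cluster
    mk(start - 3, "asthma baseline mention"),
    mk(start - 30, "asthma too old for baseline")
  )
  event <- list(group_id = "asthma", cluster_id = 1L,
                start_date = start, end_date = start + 1)
  sets <- fetch_sets(event, tw, model, groups, tnt_config())
  expect_equal(sort(sets$gist$text), c("asthma again", "asthma bad today"))
  expect_equal(sets$baseline$text, "asthma baseline mention")
  expect_equal(sets$baseline_range, c(start - 28, start - 1))
  expect_true(sets$unsummarisable)  # 2 < 30
  cfg2 <- tnt_config(min_event_tweets = 2)
  expect_false(fetch_sets(event, tw, model, groups, cfg2)$unsummarisable)
})

test_that("the stopword list is the standard list plus the corpus top-n", {
  corpus <- c(rep("lol", 5), rep("lol wat", 10), "rare token here")
  sw <- build_stopwords(corpus, top_n = 2)
  expect_true(all(c("lol", "wat") %in% sw))
  expect_false("rare" %in% sw)
  expect_true("the" %in% sw)  # from the standard list
  expect_equal(build_stopwords(corpus, standard_list = character(),
                               top_n = 0), character())
  # the selected top-n agrees with an independent frequency count
  set.seed(52)
  vocab <- sprintf("w%02d", 1:40)
  texts <- replicate(300, paste(sample(vocab, 5, replace = TRUE,
                                       prob = 40:1), collapse = " "))
  sw <- build_stopwords(texts, standard_list = character(), top_n = 10)
  freq <- sort(table(unlist(strsplit(texts, " "))), decreasing = TRUE)
  cut <- as.integer(freq[10])
  expect_setequal(sw, names(freq)[as.integer(freq) >= cut])
})

test_that("candidate n-grams respect the document-fraction threshold", {
  gist <- c(rep("smog in town", 3), rep("clear blue sky", 36),
            "smogless day")  # 40 tweets, "smog" in 3
  cands <- extract_candidates(gist, stopwords = "in", doc_fraction = 0.05)
  expect_true("smog" %in% cands)  # ceil(0.05 * 40) = 2 <= 3
  gist1 <- c("smog in town", rep("clear blue sky", 39))
  expect_false("smog" %in% extract_candidates(gist1, "in", 0.05))
  # bigrams join adjacent survivors after stopword removal
  cands <- extract_candidates(rep("bad smog in the air", 2),
                              stopwords = c("in", "the"), doc_fraction = 0.05)
  expect_true(all(c("bad smog", "smog air") %in% cands))
  expect_false("the air" %in% cands)
})

test_that("candidate sets equal a brute-force recount on random gists", {
  set.seed(53)
  vocab <- c("aa", "bb", "cc", "dd", "ee", "in", "the")
  sw <- c("in", "the")
  for (trial in 1:10) {
    gist <- replicate(sample(20:40, 1),
                      paste(sample(vocab, 4, replace = TRUE), collapse = " "))
    cands <- extract_candidates(gist, sw, 0.1)
    # oracle: quadratic scan over every tweet's n-grams
    per <- lapply(strsplit(gist, " "), function(tk) {
      tk <- tk[!tk %in% sw]
      grams <- tk
      if (length(tk) >= 2) grams <- c(grams, paste(tk[-length(tk)], tk[-1]))
      unique(grams)
    })
    all_grams <- unique(unlist(per))
    keep <- vapply(all_grams, function(g)
      sum(vapply(per, function(p) g %in% p, TRUE)) >=
        ceiling(0.1 * length(gist)), TRUE)
    expect_setequal(cands, sort(all_grams[keep]))
  }
})

test_that("fisher_p is the one-sided hypergeometric tail", {
  expect_equal(fisher_p(0, 10, 5, 10), 1)
  # hand case: 8/10 gist vs 2/10 baseline = tail over gist-with in {8,9,10}
  p <- fisher_p(8, 10, 2, 10)
  expect_equal(p, oracle_fisher_p(8, 10, 2, 10), tolerance = 1e-12)
  expect_lt(p, 0.05)
  # equal proportions with large margins are not significant
  expect_gt(fisher_p(10, 30, 10, 30), 0.05)
  # all-zero table
  expect_equal(fisher_p(0, 10, 0, 10), 1)
  # agreement with the standard library implementation on random tables
  set.seed(54)
  for (trial in 1:25) {
    g <- sample(2:25, 1); b <- sample(2:25, 1)
    gw <- sample(0:g, 1); bw <- sample(0:b, 1)
    tab <- matrix(c(gw, g - gw, bw, b - bw), 2, byrow = TRUE)
    expect_equal(fisher_p(gw, g, bw, b),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("term selection keeps the top unigrams/bigrams and appends the keyword", {
  tab <- data.frame(
    ngram = c("smog", "pollution", "dust", "air pollution", "saharan dust",
              "blue sky"),
    n = c(1, 1, 1, 2, 2, 2),
    gist_with = c(12, 10, 8, 9, 7, 2),
    gist_without = 30 - c(12, 10, 8, 9, 7, 2),
    baseline_with = c(0, 0, 1, 0, 0, 2),
    baseline_without = 60 - c(0, 0, 1, 0, 0, 2),
    p_value = c(1e-8, 1e-6, 1e-4, 1e-7, 1e-5, 0.4),
    stringsAsFactors = FALSE)
  sel <- select_terms(tab, "asthma", alpha = 0.05, k_uni = 2, k_bi = 2)
  expect_equal(sel$significant,
               c("smog", "pollution", "air pollution", "saharan dust"))
  expect_equal(sel$terms, c(sel$significant, "asthma"))
  expect_lte(length(sel$terms), 5)
  # nothing significant: fall back to the primary keyword alone
  tab$p_value <- 0.5
  sel <- select_terms(tab, "asthma")
  expect_equal(sel$terms, "asthma")
  expect_equal(sel$significant, character())
  # the primary keyword is deduplicated when it wins on its own
  tab$p_value <- c(1e-8, 0.5, 0.5, 0.5, 0.5, 0.5)
  tab$ngram[1] <- "asthma"
  sel <- select_terms(tab, "asthma")
  expect_equal(sel$terms, "asthma")
})

test_that("ties in term selection break by gist count then lexicographically", {
  tab <- data.frame(
    ngram = c("bb", "aa", "cc"), n = 1,
    gist_with = c(5, 5, 9), gist_without = 5,
    baseline_with = 0, baseline_without = 10,
    p_value = c(0.01, 0.01, 0.01), stringsAsFactors = FALSE)
  sel <- select_terms(tab, "kk", k_uni = 2, k_bi = 0)
  expect_equal(sel$significant, c("cc", "aa"))
})
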