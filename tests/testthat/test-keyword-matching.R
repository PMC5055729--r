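# Tokenisation, keyword-group phrase matching, and the self-report noise
# filter.

test_that("tokeniser lowercases, strips URLs/mentions/punctuation, keeps hashtag words", {
  expect_equal(tokenize("I can’t breathe #asthma #smog")[[1]],
               c("i", "can’t", "breathe", "asthma", "smog"))
  expect_equal(tokenize("")[[1]], character())
  expect_equal(tokenize("Visit http://x.co @bob NOW!!")[[1]],
               c("visit", "now"))
  # idempotent: retokenising the joined tokens changes nothing
  tk <- tokenize("Sore THROAT & a cough... www.x.org")[[1]]
  expect_equal(tokenize(paste(tk, collapse = " "))[[1]], tk)
})

test_that("group matching is phrase-based, case-insensitive and consolidated", {
  groups <- read_keyword_groups()
  m <- match_groups("so AMAZED right now", groups)[[1]]
  expect_equal(m, "surprise")
  # multi-word alias matches across two tokens; two groups can match one tweet
  m <- match_groups("sore throat and a cough", groups)[[1]]
  expect_setequal(m, c("sore throat", "cough"))
  # several aliases of one group still yield the group once
  vomit <- make_groups(vomit = c("throwing up", "being sick"))
  m <- match_groups("being sick of throwing up", vomit)[[1]]
  expect_equal(m, "vomit")
  # token phrases, not substrings: "flute" must not match "flu"
  expect_equal(match_groups("playing the flute", groups)[[1]], character())
})

test_that("adding an alias can only grow a group's match set", {
  set.seed(7)
  vocab <- c("cough", "nasty", "day", "week", "hacking", "chesty", "fine")
  texts <- replicate(60, paste(sample(vocab, 5, replace = TRUE),
                               collapse = " "))
  g1 <- make_groups(cough = c("hacking cough"))
  g2 <- make_groups(cough = c("hacking cough", "chesty"))
  m1 <- lengths(match_groups(texts, g1)) > 0
  m2 <- lengths(match_groups(texts, g2)) > 0
  expect_true(all(m2[m1]))
  # duplicated aliases change nothing
  g3 <- make_groups(cough = c("hacking cough", "hacking cough"))
  g3$cough$aliases <- c("hacking cough", "hacking cough")
  expect_equal(match_groups(texts, g3), match_groups(texts, g1))
})

test_that("a sentiment scorer adds pseudo-groups that flow into aggregation", {
  matched <- list(character(), "flu", character())
  scores <- c(5, -4.5, 0)
  aug <- add_sentiment_groups(matched, scores)
  expect_equal(aug[[1]], "very positive")
  expect_equal(aug[[2]], c("flu", "very negative"))
  expect_equal(aug[[3]], character())
  # pseudo-groups become count series via the precomputed matched attribute
  model <- make_square_model(52, -1.5)
  tw <- make_tweets(c("great day", "flu misery", "neutral"))
  attr(tw, "matched") <- aug
  series <- aggregate_counts(tw, model, make_groups(flu = character()),
                             as.Date(c("2014-04-02", "2014-04-02")))
  expect_setequal(vapply(series, `[[`, "", "group_id"),
                  c("flu", "very positive", "very negative"))
})

test_that("noise filter separates a linearly separable labelled set", {
  set.seed(11)
  vocab <- c("flu", "cough", "research", "news", "report", "today", "bad")
  texts <- character(200)
  labels <- character(200)
  for (i in 1:200) {
    base <- sample(vocab, 4, replace = TRUE)
    if (i %% 2 == 0) {
      texts[i] <- paste(c(base, "me"), collapse = " ")
      labels[i] <- "report"
    } else {
      texts[i] <- paste(base, collapse = " ")
      labels[i] <- "not_report"
    }
  }
  model <- train_noise_filter(texts, labels, seed = 1, quiet = TRUE)
  expect_gte(model$holdout_accuracy, 0.95)
  # deterministic given the seed
  model2 <- train_noise_filter(texts, labels, seed = 1, quiet = TRUE)
  expect_equal(model$weights, model2$weights)
  expect_error(train_noise_filter(texts[labels == "report"],
                                  labels[labels == "report"]),
               "at least two examples")
})

test_that("undecidable labelled sets give chance-level held-out accuracy", {
  texts <- rep(c("flu got me today", "flu got me today"), 60)
  labels <- rep(c("report", "not_report"), 60)
  model <- train_noise_filter(texts, labels, seed = 3, quiet = TRUE)
  expect_lt(abs(model$holdout_accuracy - 0.5), 0.2)
})

test_that("noise filter application is identity when absent, subset otherwise", {
  tw <- make_tweets(c("flu got me", "flu research", "me and my flu"))
  expect_identical(apply_noise_filter(tw, NULL), tw)
  model <- structure(list(vocabulary = c(me = 1L), weights = 1,
                          bias = -0.5, threshold = 0),
                     class = "noise_filter")
  kept <- apply_noise_filter(tw, model)
  expect_equal(kept$text, c("flu got me", "me and my flu"))
  # order preserved, subset of input
  expect_true(all(kept$id %in% tw$id))
  expect_false(is.unsorted(match(kept$id, tw$id)))
  # everything below threshold -> empty
  model$bias <- -10
  expect_equal(nrow(apply_noise_filter(tw, model)), 0)
})

test_that("noise filters round-trip through JSON", {
  set.seed(2)
  texts <- c(paste("flu got me down today number", 1:12),
             paste("flu research conference paper number", 1:12))
  labels <- rep(c("report", "not_report"), each = 12)
  model <- train_noise_filter(texts, labels, seed = 5, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_noise_filter(model, path)
  back <- read_noise_filter(path)
  expect_equal(back$vocabulary, model$vocabulary)
  expect_equal(back$weights, model$weights)
  expect_equal(back$bias, model$bias)
})
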