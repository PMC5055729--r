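# TF-IDF vectors, PCSS coherence, title relatedness and article ranking.

vec <- function(...) {
  v <- c(...)
  v[v != 0]
}

test_that("tf-idf weights follow tf * ln(N/df) over the document set", {
  docs <- list(c("a", "a", "b"), c("a", "c"), c("b", "c", "c"))
  vs <- tfidf_vectors(docs)
  # "a": df 2 -> idf ln(3/2); doc1 tf 2
  expect_equal(unname(vs[[1]]["a"]), 2 * log(3 / 2))
  expect_equal(unname(vs[[2]]["c"]), 1 * log(3 / 2))
  expect_equal(unname(vs[[3]]["c"]), 2 * log(3 / 2))
  # identical documents -> identical vectors, cosine 1
  vs2 <- tfidf_vectors(list(c("x", "y"), c("x", "y"), c("z")))
  expect_equal(vs2[[1]], vs2[[2]])
  expect_equal(cosine_sim(vs2[[1]], vs2[[2]]), 1)
  # a term in every document vanishes (idf 0)
  vs3 <- tfidf_vectors(list(c("a", "b"), c("a", "c"), c("a", "d")))
  expect_false(any(vapply(vs3, function(v) "a" %in% names(v), TRUE)))
  # empty document
  expect_equal(length(tfidf_vectors(list(character(), c("a")))[[1]]), 0)
})

test_that("pcss matches its closed forms and the hand-worked example", {
  v <- vec(a = 1, b = 2)
  expect_equal(pcss(list(v, v, v)), 1)
  orth <- list(vec(a = 1), vec(b = 1), vec(c = 1))
  expect_equal(pcss(orth), 0)
  # vectors (1,0), (1,1)/sqrt(2), (0,1): cosines {0.7071, 0, 0.7071};
  # mean 0.4714, population sd 0.3333 -> PCSS 0.1381
  triple <- list(vec(x = 1), vec(x = 1 / sqrt(2), y = 1 / sqrt(2)),
                 vec(y = 1))
  expect_equal(pcss(triple), 0.1381, tolerance = 1e-3)
  expect_error(pcss(list(v)), "at least two")
  # permutation invariance and positive-scaling invariance
  set.seed(61)
  vs <- lapply(1:5, function(i)
    vec(a = runif(1), b = runif(1), c = runif(1)))
  expect_equal(pcss(vs), pcss(rev(vs)))
  vs_scaled <- vs
  vs_scaled[[2]] <- vs_scaled[[2]] * 17
  expect_equal(pcss(vs_scaled), pcss(vs))
  # PCSS <= 1, with equality only when all cosines are 1
  expect_lte(pcss(vs), 1)
})

test_that("cross_pcss covers all cross pairs and is symmetric", {
  v <- vec(a = 1)
  expect_equal(cross_pcss(list(v), list(v)), 1)
  expect_equal(cross_pcss(list(vec(a = 1)), list(vec(b = 1), vec(c = 1))), 0)
  a <- list(vec(x = 1), vec(x = 1, y = 1))
  b <- list(vec(x = 1), vec(y = 1), vec(x = 2, y = 2))
  # oracle: mean - population sd over the 6 cross cosines
  cosines <- c(1, 0, 1 / sqrt(2),
               1 / sqrt(2), 1 / sqrt(2), 1)
  expect_equal(cross_pcss(a, b),
               mean(cosines) - sqrt(mean((cosines - mean(cosines))^2)))
  expect_equal(cross_pcss(a, b), cross_pcss(b, a))
  expect_error(cross_pcss(list(), b), "non-empty")
})

test_that("news search filters by date and ranks planted articles first", {
  sc <- scenario_config(seed = 77)
  stream <- generate_stream(sc)
  out <- generate_news(sc, stream$truth)
  ev <- sc$events[[1]]
  hits <- search_news(out$news, "smog", c(ev$dates[1], ev$dates[2] + 1))
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$article_id %in% out$truth$planted_article_ids))
  expect_true(all(hits$date >= ev$dates[1] & hits$date <= ev$dates[2] + 1))
  expect_false(is.unsorted(rev(hits$relevance)))
  # out-of-range window returns nothing for the planted story
  none <- search_news(out$news, "smog",
                      c(sc$date_range[1], sc$date_range[1] + 3))
  expect_equal(nrow(none), 0)
})

test_that("title vectors enumerate unigrams, bigrams and trigrams", {
  # two titles, so features of the first do not all have df = N (idf 0)
  vs <- title_vectors(c("air pollution reaches high levels",
                        "football cup tonight"), stopwords = character())
  feats <- names(vs[[1]])
  expect_true("air pollution" %in% feats)
  expect_true("air pollution reaches" %in% feats)
  identical_titles <- title_vectors(
    c("air pollution alert", "air pollution alert", "other thing entirely"),
    stopwords = character())
  expect_equal(cosine_sim(identical_titles[[1]], identical_titles[[2]]), 1)
  disjoint <- title_vectors(c("air pollution", "football cup", "third one"),
                            stopwords = character())
  expect_equal(cosine_sim(disjoint[[1]], disjoint[[2]]), 0)
})

test_that("coherence and relatedness gate the good terms", {
  cfg <- tnt_config()
  # lone coherent term: not good
  mk_res <- function(term, titles, pcss_val, coherent = TRUE) {
    list(term = term,
         articles = data.frame(article_id = paste0(term, seq_along(titles)),
                               title = titles, body = titles,
                               date = as.Date("2014-04-02"), source = "s",
                               url = "u", relevance = 1,
                               stringsAsFactors = FALSE),
         body_pcss = pcss_val, coherent = coherent,
         related_terms = character(), good = FALSE)
  }
  story <- c("smog pollution health warning", "smog pollution city alert")
  other <- c("football cup final", "football cup tonight")
  # IDF corpus: the full news corpus titles, as summarise_event supplies
  corpus <- c(story, other, "market shares tumble", "monsoon rains arrive")
  res <- filter_terms(list(mk_res("smog", story, 0.3)), cfg,
                      idf_titles = corpus)
  expect_false(res[[1]]$good)
  # two terms retrieving the same story: both good
  res <- filter_terms(list(mk_res("smog", story, 0.3),
                           mk_res("pollution", story, 0.2)), cfg,
                      idf_titles = corpus)
  expect_true(res[[1]]$good && res[[2]]$good)
  expect_equal(res[[1]]$related_terms, "pollution")
  # a coherent but unrelated term stays not good
  res <- filter_terms(list(mk_res("smog", story, 0.3),
                           mk_res("pollution", story, 0.2),
                           mk_res("football", other, 0.5)), cfg,
                      idf_titles = corpus)
  expect_false(res[[3]]$good)
  expect_true(res[[1]]$good)
  # below the coherence threshold the term is out regardless
  res <- filter_terms(list(mk_res("smog", story, -0.2, coherent = FALSE),
                           mk_res("pollution", story, 0.2)), cfg,
                      idf_titles = corpus)
  expect_false(res[[1]]$good)
  expect_false(res[[2]]$good)  # its only candidate partner is incoherent
})

test_that("article ranking scores against the mean vector and deduplicates", {
  mk_article <- function(id, body) {
    data.frame(article_id = id, title = body, body = body,
               date = as.Date("2014-04-02"), source = "s", url = "u",
               relevance = 1, stringsAsFactors = FALSE)
  }
  # one article covering the union of the others' vocabulary ranks first
  arts <- rbind(mk_article("a1", "smog warning"),
                mk_article("a2", "dust cloud"),
                mk_article("a3", "smog warning dust cloud extra"))
  res <- list(list(term = "t", articles = arts, body_pcss = 0.5,
                   coherent = TRUE, related_terms = "x", good = TRUE))
  ranked <- rank_articles(res, top_k = 5, stopwords = character())
  expect_equal(ranked$article_id[1], "a3")
  # identical articles: all scores 1, input order preserved
  same <- rbind(mk_article("b1", "same text"), mk_article("b2", "same text"),
                mk_article("b3", "same text"))
  res2 <- list(list(term = "t", articles = same, body_pcss = 1,
                    coherent = TRUE, related_terms = "x", good = TRUE))
  ranked2 <- rank_articles(res2, top_k = 2, stopwords = character())
  expect_equal(ranked2$article_id, c("b1", "b2"))
  # duplicates across terms keep the higher score once
  res3 <- list(res[[1]], list(term = "t2", articles = arts[3:1, ],
                              body_pcss = 0.5, coherent = TRUE,
                              related_terms = "x", good = TRUE))
  ranked3 <- rank_articles(res3, top_k = 5, stopwords = character())
  expect_equal(anyDuplicated(ranked3$article_id), 0L)
  # no good terms -> empty result ("no newsworthy match")
  expect_equal(nrow(rank_articles(list())), 0)
})
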