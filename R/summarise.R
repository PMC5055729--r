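# Terms-News-Tweets (TNT) event summarisation: differential terms from gist
# vs baseline, coherence-filtered news linkage, and ranked representative
# tweets (gist top tweets, GTT, and summary top tweets, STT).

#' Summarise a detected event
#'
#' Runs the full summarisation chain for one event: fetch gist and baseline
#' tweet sets, build the event stopword list, extract and test candidate
#' terms, search the news corpus per term, filter terms by article-set
#' coherence (PCSS) and cross-term title relatedness, rank the surviving
#' articles, and rank the gist (GTT) and term-filtered (STT) tweets.
#'
#' @param event an alarm record from [detect_events()] (an element of
#'   `detection$alarms`).
#' @param tweets the full tweet stream.
#' @param model a `cluster_model`.
#' @param groups keyword groups.
#' @param news article data.frame from [read_news_corpus()] (may be empty).
#' @param config a [tnt_config()].
#' @param stopword_corpus tweet texts used for the frequency-derived stopword
#'   extension; defaults to the full stream.
#' @return an object of class `tnt_summary`: event id, selected terms and
#'   their table, good terms, top articles, `gtt`, `stt` and `stt_source`.
#' @export
summarise_event <- function(event, tweets, model, groups, news,
                            config = tnt_config(), stopword_corpus = NULL) {
  config <- as_tnt_config(config)
  sets <- fetch_sets(event, tweets, model, groups, config)
  base <- list(event_id = event$alarm_id, group_id = event$group_id,
               cluster_id = event$cluster_id,
               gist_size = nrow(sets$gist), baseline_size = nrow(sets$baseline),
               unsummarisable = sets$unsummarisable)
  if (sets$unsummarisable) {
    return(structure(c(base, list(
      terms = event$group_id, significant_terms = character(),
      good_terms = character(), term_table = NULL,
      top_articles = news[0, , drop = FALSE],
      gtt = sets$gist[0, , drop = FALSE],
      stt = NULL, stt_source = "unavailable")), class = "tnt_summary"))
  }

  if (is.null(stopword_corpus)) stopword_corpus <- tweets$text
  stopwords <- build_stopwords(stopword_corpus,
                               top_n = config$stopword_top_n)
  candidates <- extract_candidates(sets$gist$text, stopwords,
                                   config$ngram_doc_fraction)
  if (length(candidates) > 0) {
    tab <- term_table(candidates, sets$gist$text, sets$baseline$text,
                      stopwords)
    sel <- select_terms(tab, event$group_id, config$fisher_alpha,
                        config$top_k_unigrams, config$top_k_bigrams)
  } else {
    tab <- NULL
    sel <- list(terms = event$group_id, significant = character())
  }

  search_range <- c(event$start_date, event$end_date + 1)
  results <- search_terms(sel$terms, news, search_range, config, stopwords)
  results <- filter_terms(results, config, stopwords,
                          idf_titles = news$title)
  good_terms <- vapply(Filter(function(r) isTRUE(r$good), results),
                       `[[`, "", "term")
  top_articles <- rank_articles(results, config$top_k_articles, stopwords)

  gtt <- rank_tweets(sets$gist, config$top_k_tweets, stopwords)
  chosen <- select_tweet_set(sets$gist, sel$significant, good_terms,
                             stopwords)
  stt <- if (chosen$stt_source == "unavailable") NULL else
    rank_tweets(chosen$tweets, config$top_k_tweets, stopwords)

  structure(c(base, list(
    terms = sel$terms, significant_terms = sel$significant,
    good_terms = good_terms, term_table = tab,
    term_results = lapply(results, function(r)
      list(term = r$term, n_articles = nrow(r$articles),
           body_pcss = r$body_pcss, coherent = r$coherent,
           related_terms = r$related_terms, good = r$good)),
    top_articles = top_articles,
    gtt = gtt, stt = stt, stt_source = chosen$stt_source)),
    class = "tnt_summary")
}

#' @export
print.tnt_summary <- function(x, ...) {
  cat(sprintf("Event %s (%s, cluster %d): %d gist / %d baseline tweets\n",
              x$event_id, x$group_id, x$cluster_id, x$gist_size,
              x$baseline_size))
  if (isTRUE(x$unsummarisable)) {
    cat("  gist below the minimum size: not summarised\n")
    return(invisible(x))
  }
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  cat("  good terms:",
      if (length(x$good_terms)) paste(x$good_terms, collapse = ", ")
      else "(none: no newsworthy match)", "\n")
  if (nrow(x$top_articles)) {
    cat("  top articles:\n")
    for (i in seq_len(nrow(x$top_articles))) {
      cat(sprintf("    %d. %s (%s, score %.3f)\n", i,
                  x$top_articles$title[i], format(x$top_articles$date[i]),
                  x$top_articles$score[i]))
    }
  }
  if (nrow(x$gtt)) {
    cat("  GTT:", sprintf("\"%s\"", x$gtt$text[1]), "...\n")
  }
  if (!is.null(x$stt) && nrow(x$stt)) {
    cat(sprintf("  STT (%s):", x$stt_source),
        sprintf("\"%s\"", x$stt$text[1]), "...\n")
  }
  invisible(x)
}

#' Serialise event summaries as JSON
#'
#' @param summaries list of `tnt_summary` objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  if (inherits(summaries, "tnt_summary")) summaries <- list(summaries)
  payload <- lapply(summaries, function(s) {
    list(event_id = s$event_id, group = s$group_id, cluster = s$cluster_id,
         unsummarisable = s$unsummarisable,
         terms = as.list(s$terms), good_terms = as.list(s$good_terms),
         articles = if (nrow(s$top_articles)) lapply(
           seq_len(nrow(s$top_articles)), function(i) list(
             article_id = s$top_articles$article_id[i],
             title = s$top_articles$title[i],
             url = s$top_articles$url[i],
             score = s$top_articles$score[i])) else list(),
         gtt = as.list(s$gtt$text), stt = as.list(s$stt$text),
         stt_source = s$stt_source)
  })
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
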