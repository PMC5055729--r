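# Representative-tweet selection: choose the tweet set (gist / term-filtered
# gist / good-term-filtered gist) and rank by cosine similarity to the set's
# mean TF-IDF vector.

#' Select the summary tweet set
#'
#' Fallback chain: gist tweets containing a good search term (source
#' `"good_terms"`); otherwise gist tweets containing an extracted term beyond
#' the primary keyword (source `"extracted_terms"`); otherwise no summary set
#' (source `"unavailable"`, gist-top-tweets only). Containment is tested on
#' stopword-free token phrases with the same matcher as term extraction.
#'
#' @param gist gist tweet data.frame.
#' @param extracted_terms significant terms from [select_terms()] (without
#'   the appended primary keyword).
#' @param good_terms terms that passed the news coherence/relatedness filter.
#' @param stopwords stopword set used during extraction.
#' @return list with `tweets` (possibly empty) and `stt_source`.
#' @export
select_tweet_set <- function(gist, extracted_terms, good_terms,
                             stopwords = standard_stopwords()) {
  stopifnot(nrow(gist) > 0)
  match_any <- function(terms) {
    phr <- lapply(terms, function(tm) tokenize1(tm))
    toks <- lapply(tokenize(gist$text), drop_stopwords,
                   stopwords = stopwords)
    keep <- vapply(toks, function(tk) {
      any(vapply(phr, contains_phrase, TRUE, tokens = tk))
    }, TRUE)
    gist[keep, , drop = FALSE]
  }
  if (length(good_terms) > 0) {
    sub <- match_any(good_terms)
    if (nrow(sub) > 0) return(list(tweets = sub, stt_source = "good_terms"))
  }
  if (length(extracted_terms) > 0) {
    sub <- match_any(extracted_terms)
    if (nrow(sub) > 0) return(list(tweets = sub,
                                   stt_source = "extracted_terms"))
  }
  list(tweets = gist[0, , drop = FALSE], stt_source = "unavailable")
}

#' Rank tweets against their set's mean vector
#'
#' Per-tweet TF-IDF vectors (tokenised, stopwords removed, unigrams, no
#' stemming, document frequencies over the tweet set) are ranked by cosine
#' similarity to the arithmetic-mean vector. Ties break by earlier timestamp,
#' then id.
#'
#' @param tweets tweet data.frame.
#' @param top_k number of tweets returned.
#' @param stopwords stopword set.
#' @return the top `top_k` rows of `tweets` with a `score` column.
#' @export
rank_tweets <- function(tweets, top_k = 5,
                        stopwords = standard_stopwords()) {
  if (nrow(tweets) == 0) {
    out <- tweets
    out$score <- numeric(0)
    return(out)
  }
  toks <- lapply(tokenize(tweets$text), drop_stopwords,
                 stopwords = stopwords)
  vecs <- tfidf_vectors(toks, n_max = 1L)
  mv <- mean_vector(vecs)
  sc <- vapply(vecs, cosine_sim, 0, b = mv)
  ord <- order(-sc, tweets$timestamp, tweets$id)
  ord <- utils::head(ord, top_k)
  out <- tweets[ord, , drop = FALSE]
  out$score <- sc[ord]
  rownames(out) <- NULL
  out
}
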