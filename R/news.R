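# News linkage: search a local news corpus per extracted term, score each
# term's retrieved article set for topical coherence with the pairwise cosine
# similarity score (PCSS) over TF-IDF body vectors, require every term's
# articles to be related to at least one other term's via a title cross-PCSS
# check, and rank the surviving articles against their set's mean vector.

#' Search the local news corpus for a term
#'
#' Ranked retrieval over articles dated within `date_range`: documents are
#' TF-IDF vectors over title + body tokens with title tokens counted twice,
#' the query vector carries the term's tokens, and articles are ranked by
#' cosine similarity. Zero-scoring articles are not returned. Ties break by
#' date, then article id.
#'
#' @param corpus article data.frame from [read_news_corpus()].
#' @param term search term (possibly multi-word).
#' @param date_range length-2 `Date` vector (inclusive); event callers pass
#'   `[start, end + 1]` to admit next-day reporting.
#' @param limit maximum number of articles returned.
#' @param stopwords stopword set used for document and query tokens.
#' @return subset of `corpus` with an added `relevance` column, best first.
#' @export
search_news <- function(corpus, term, date_range, limit = 10,
                        stopwords = standard_stopwords()) {
  date_range <- as.Date(date_range)
  in_range <- corpus[corpus$date >= date_range[1] &
                       corpus$date <= date_range[2], , drop = FALSE]
  if (nrow(in_range) == 0) return(cbind(in_range, relevance = numeric()))
  title_toks <- tokenize(in_range$title)
  body_toks <- tokenize(in_range$body)
  doc_toks <- mapply(function(ti, bo) {
    drop_stopwords(c(ti, ti, bo), stopwords)  # title counted double
  }, title_toks, body_toks, SIMPLIFY = FALSE)
  term_toks <- drop_stopwords(tokenize1(term), character())
  vecs <- tfidf_vectors(c(doc_toks, list(term_toks)), n_max = 1L)
  qv <- vecs[[length(vecs)]]
  if (length(qv) == 0) {
    # term absent from no document or present in all: fall back to raw
    # presence weighting so a ubiquitous term still retrieves
    qv <- stats::setNames(rep(1, length(term_toks)), term_toks)
  }
  scores <- vapply(vecs[seq_len(nrow(in_range))], cosine_sim, 0, b = qv)
  # presence fallback: when idf zeroes the query terms out (term in every
  # in-range document), rank by fractional token overlap instead
  raw_scores <- vapply(doc_toks, function(dt) {
    if (length(dt) == 0 || length(term_toks) == 0) return(0)
    sum(term_toks %in% dt) / length(term_toks)
  }, 0)
  scores <- ifelse(scores > 0, scores, raw_scores * 1e-6)
  keep <- which(scores > 0)
  if (length(keep) == 0) return(cbind(in_range[0, , drop = FALSE],
                                      relevance = numeric()))
  ord <- keep[order(-scores[keep], in_range$date[keep],
                    in_range$article_id[keep])]
  ord <- utils::head(ord, limit)
  out <- in_range[ord, , drop = FALSE]
  out$relevance <- scores[ord]
  rownames(out) <- NULL
  out
}

#' TF-IDF body vectors of a retrieved article set
#'
#' Tokens of title + body, stopwords removed, Lancaster-stemmed; weights are
#' `tf * ln(N / df)` with document frequencies taken over the retrieved set
#' itself, so a stem present in every retrieved article vanishes.
#'
#' @param articles article data.frame (a retrieved set).
#' @param stopwords stopword set.
#' @return list of weighted term vectors, one per article.
#' @export
body_vectors <- function(articles, stopwords = standard_stopwords()) {
  toks <- lapply(seq_len(nrow(articles)), function(i) {
    lancaster_stem(drop_stopwords(
      c(tokenize1(articles$title[i]), tokenize1(articles$body[i])),
      stopwords))
  })
  tfidf_vectors(toks, n_max = 1L)
}

#' TF-IDF title vectors
#'
#' Titles only, stopwords removed, no stemming; features are all unigrams,
#' bigrams and trigrams of the surviving tokens. Document frequencies come
#' from `idf_titles`; by default the vectorised titles themselves. For the
#' relatedness check the full news corpus titles should be supplied: with IDF
#' taken only over the compared sets, vocabulary shared by every retrieved
#' title — the evidence that two searches hit the same story — would get
#' `idf = 0` and vanish.
#'
#' @param titles character vector of titles to vectorise.
#' @param stopwords stopword set.
#' @param idf_titles character vector of titles forming the IDF corpus
#'   (defaults to `titles`). Features unseen in it are treated as df = 1.
#' @return list of weighted term vectors, one per title.
#' @export
title_vectors <- function(titles, stopwords = standard_stopwords(),
                          idf_titles = titles) {
  feats <- function(tt) {
    lapply(lapply(tokenize(tt), drop_stopwords, stopwords = stopwords),
           ngram_tokens, n_max = 3L)
  }
  idf_feats <- feats(idf_titles)
  n_docs <- length(idf_feats)
  df <- table(unlist(lapply(idf_feats, unique), use.names = FALSE))
  target <- feats(titles)
  lapply(target, function(f) {
    if (length(f) == 0L) return(stats::setNames(numeric(), character()))
    tf <- table(f)
    d <- df[names(tf)]
    d[is.na(d)] <- 1
    w <- as.numeric(tf) * log(n_docs / as.numeric(d))
    w <- stats::setNames(w, names(tf))
    w[w != 0]
  })
}

#' Title relatedness between two terms' article sets
#'
#' Cross-set PCSS over unigram/bigram/trigram title vectors. `idf_titles`
#' supplies the IDF corpus (pass the full news corpus titles; defaults to the
#' union of the two sets).
#'
#' @param titles_a,titles_b character vectors of article titles.
#' @param stopwords stopword set.
#' @param idf_titles IDF corpus titles.
#' @return numeric scalar.
#' @export
title_relatedness <- function(titles_a, titles_b,
                              stopwords = standard_stopwords(),
                              idf_titles = c(titles_a, titles_b)) {
  va <- title_vectors(titles_a, stopwords, idf_titles)
  vb <- title_vectors(titles_b, stopwords, idf_titles)
  cross_pcss(va, vb)
}

#' Run the news searches for a set of terms
#'
#' @param terms character vector of search terms.
#' @param corpus article data.frame.
#' @param date_range search window (see [search_news()]).
#' @param config a [tnt_config()].
#' @param stopwords stopword set.
#' @return list of term search results: `term`, `articles`, `body_pcss`,
#'   `coherent` (body PCSS at or above the threshold; a term retrieving fewer
#'   than two articles is never coherent).
#' @export
search_terms <- function(terms, corpus, date_range, config = tnt_config(),
                         stopwords = standard_stopwords()) {
  config <- as_tnt_config(config)
  lapply(terms, function(term) {
    arts <- search_news(corpus, term, date_range, config$news_per_term,
                        stopwords)
    if (nrow(arts) >= 2) {
      bp <- pcss(body_vectors(arts, stopwords))
    } else {
      bp <- NA_real_
    }
    list(term = term, articles = arts, body_pcss = bp,
         coherent = !is.na(bp) && bp >= config$pcss_threshold,
         related_terms = character(), good = FALSE)
  })
}

#' Coherence and relatedness filtering of term search results
#'
#' A term is coherent when its body PCSS is at or above `pcss_threshold`.
#' Among coherent terms, two terms are related when the cross-set title PCSS
#' is at or above `relatedness_threshold`. A term is good when it is coherent
#' and related to at least one other coherent term; a lone coherent term is
#' not good.
#'
#' @param results list from [search_terms()].
#' @param config a [tnt_config()].
#' @param stopwords stopword set.
#' @param idf_titles IDF corpus for the title vectors (pass the full news
#'   corpus titles; `NULL` falls back to the per-pair union).
#' @return `results` with `related_terms` and `good` filled in.
#' @export
filter_terms <- function(results, config = tnt_config(),
                         stopwords = standard_stopwords(),
                         idf_titles = NULL) {
  config <- as_tnt_config(config)
  coherent_idx <- which(vapply(results, `[[`, TRUE, "coherent"))
  if (length(coherent_idx) >= 2) {
    for (a in seq_along(coherent_idx)) {
      for (b in seq_along(coherent_idx)) {
        if (b <= a) next
        i <- coherent_idx[a]
        j <- coherent_idx[b]
        rel <- if (is.null(idf_titles)) {
          title_relatedness(results[[i]]$articles$title,
                            results[[j]]$articles$title, stopwords)
        } else {
          title_relatedness(results[[i]]$articles$title,
                            results[[j]]$articles$title, stopwords,
                            idf_titles)
        }
        if (rel >= config$relatedness_threshold) {
          results[[i]]$related_terms <- c(results[[i]]$related_terms,
                                          results[[j]]$term)
          results[[j]]$related_terms <- c(results[[j]]$related_terms,
                                          results[[i]]$term)
        }
      }
    }
  }
  for (i in seq_along(results)) {
    results[[i]]$good <- results[[i]]$coherent &&
      length(results[[i]]$related_terms) >= 1
  }
  results
}

#' Rank articles across the good terms
#'
#' Within each good term's retrieved set, articles are ranked by cosine
#' similarity to the set's arithmetic-mean TF-IDF body vector; sets are then
#' merged, deduplicated by article id keeping the higher score, and the top
#' `top_k` returned. Ties preserve the within-set input order.
#'
#' @param results filtered results from [filter_terms()].
#' @param top_k number of articles returned.
#' @param stopwords stopword set.
#' @return article data.frame with a `score` column (may be empty when no
#'   term is good: "no newsworthy match").
#' @export
rank_articles <- function(results, top_k = 5,
                          stopwords = standard_stopwords()) {
  good <- Filter(function(r) isTRUE(r$good), results)
  pieces <- list()
  for (r in good) {
    vecs <- body_vectors(r$articles, stopwords)
    mv <- mean_vector(vecs)
    sc <- vapply(vecs, cosine_sim, 0, b = mv)
    df <- r$articles
    df$score <- sc
    pieces[[length(pieces) + 1L]] <- df
  }
  if (length(pieces) == 0) {
    return(data.frame(article_id = character(), title = character(),
                      body = character(), date = as.Date(character()),
                      source = character(), url = character(),
                      relevance = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  all_df <- do.call(rbind, pieces)
  # dedupe by article id, keeping the higher score; stable order otherwise
  all_df <- all_df[order(-all_df$score), , drop = FALSE]
  all_df <- all_df[!duplicated(all_df$article_id), , drop = FALSE]
  out <- utils::head(all_df, top_k)
  rownames(out) <- NULL
  out
}
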