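# Differential term extraction for event summarisation: assemble the gist
# (the event's tweets) and a 28-day pre-event baseline, extract frequent
# unigrams/bigrams from the stopword-filtered gist, and keep those occurring
# significantly more often in the gist than in the baseline (one-sided
# Fisher's exact test).

#' Fetch gist and baseline tweet sets for an event
#'
#' The gist holds the tweets in the event's cluster matching the event's
#' keyword group within the event period; the baseline applies the same
#' filter over the `baseline_days` days strictly before the event start.
#' Events with fewer than `min_event_tweets` gist tweets are flagged
#' unsummarisable.
#'
#' @param event an alarm record from [detect_events()] (fields `group_id`,
#'   `cluster_id`, `start_date`, `end_date`).
#' @param tweets the full tweet stream.
#' @param model a `cluster_model`.
#' @param groups keyword groups.
#' @param config a [tnt_config()].
#' @return list with `gist`, `baseline` (tweet data.frames), their date
#'   ranges, and `unsummarisable`.
#' @export
fetch_sets <- function(event, tweets, model, groups, config = tnt_config()) {
  config <- as_tnt_config(config)
  cluster <- assign_cluster(cbind(tweets$lat, tweets$lon), model)
  matched <- match_groups(tweets$text, groups)
  gist_range <- c(event$start_date, event$end_date)
  baseline_range <- c(event$start_date - config$baseline_days,
                      event$start_date - 1)
  gist <- filter_gist(tweets, cluster, matched, event$group_id,
                      event$cluster_id, gist_range[1], gist_range[2])
  baseline <- filter_gist(tweets, cluster, matched, event$group_id,
                          event$cluster_id, baseline_range[1],
                          baseline_range[2])
  list(gist = gist, baseline = baseline, gist_range = gist_range,
       baseline_range = baseline_range,
       unsummarisable = nrow(gist) < config$min_event_tweets)
}

# unique unigrams + bigrams of one tweet after stopword removal; bigrams are
# formed only from adjacent surviving tokens
tweet_ngrams <- function(tokens, stopwords) {
  kept <- drop_stopwords(tokens, stopwords)
  unique(ngram_tokens(kept, n_max = 2L))
}

#' Extract candidate terms from a gist
#'
#' Unigrams and bigrams over the stopword-filtered gist occurring in at least
#' `ceil(doc_fraction * |gist|)` distinct tweets (per-tweet presence is
#' binary).
#'
#' @param gist_texts character vector of gist tweet texts (or a list of token
#'   vectors).
#' @param stopwords stopword set from [build_stopwords()].
#' @param doc_fraction minimum fraction of gist tweets containing the n-gram.
#' @return character vector of candidate n-grams (space-joined bigrams).
#' @export
extract_candidates <- function(gist_texts, stopwords, doc_fraction = 0.05) {
  toks <- if (is.list(gist_texts)) gist_texts else tokenize(gist_texts)
  n <- length(toks)
  if (n == 0) stop("extract_candidates: empty gist", call. = FALSE)
  per_tweet <- lapply(toks, tweet_ngrams, stopwords = stopwords)
  df <- table(unlist(per_tweet, use.names = FALSE))
  min_docs <- ceiling(doc_fraction * n)
  sort(names(df)[as.integer(df) >= min_docs])
}

#' One-sided Fisher exact p-value for gist enrichment
#'
#' The p-value of the 2x2 presence table (gist with/without vs baseline
#' with/without) in the gist-enriched direction: the hypergeometric tail
#' probability of a table at least as extreme, with margins fixed. Vectorised
#' over candidates.
#'
#' @param gist_with,baseline_with tweets containing the term on each side.
#' @param gist_size,baseline_size total tweets on each side.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
fisher_p <- function(gist_with, gist_size, baseline_with, baseline_size) {
  k <- gist_with + baseline_with
  n <- gist_size + baseline_size
  # P[X >= gist_with], X ~ Hypergeometric(n, k, gist_size)
  p <- stats::phyper(gist_with - 1, k, n - k, gist_size, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Candidate term table with enrichment p-values
#'
#' @param candidates character vector of candidate n-grams.
#' @param gist_texts,baseline_texts tweet texts (or token lists) of the two
#'   sides.
#' @param stopwords shared stopword set.
#' @return data.frame: ngram, n (n-gram order), per-side presence counts and
#'   `p_value`.
#' @export
term_table <- function(candidates, gist_texts, baseline_texts, stopwords) {
  g_toks <- if (is.list(gist_texts)) gist_texts else tokenize(gist_texts)
  b_toks <- if (is.list(baseline_texts)) baseline_texts
  else tokenize(baseline_texts)
  g_sets <- lapply(g_toks, tweet_ngrams, stopwords = stopwords)
  b_sets <- lapply(b_toks, tweet_ngrams, stopwords = stopwords)
  count_in <- function(sets, term) sum(vapply(sets, function(s)
    term %in% s, TRUE))
  gw <- vapply(candidates, count_in, 0L, sets = g_sets)
  bw <- vapply(candidates, count_in, 0L, sets = b_sets)
  ng <- length(g_sets)
  nb <- length(b_sets)
  data.frame(
    ngram = candidates,
    n = lengths(strsplit(candidates, " ", fixed = TRUE)),
    gist_with = as.integer(gw), gist_without = ng - as.integer(gw),
    baseline_with = as.integer(bw), baseline_without = nb - as.integer(bw),
    p_value = fisher_p(gw, ng, bw, nb),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Select search terms from the candidate table
#'
#' Among candidates with `p < alpha`, the `k_uni` most significant unigrams
#' and `k_bi` most significant bigrams are kept (ties by higher gist count,
#' then lexicographic), and the primary keyword that triggered the alarm is
#' appended (deduplicated). With no significant candidate the primary keyword
#' alone is returned and `significant` is empty, so callers can fall back to
#' gist-only summarisation.
#'
#' @param table candidate table from [term_table()].
#' @param primary_keyword the alarm's primary keyword.
#' @param alpha significance level.
#' @param k_uni,k_bi unigram and bigram slots.
#' @return list with `terms` (ordered character vector) and `significant`
#'   (the selected terms without the appended keyword).
#' @export
select_terms <- function(table, primary_keyword, alpha = 0.05, k_uni = 2,
                         k_bi = 2) {
  sig <- table[table$p_value < alpha, , drop = FALSE]
  pick <- function(sub, k) {
    if (nrow(sub) == 0 || k == 0) return(character())
    ord <- order(sub$p_value, -sub$gist_with, sub$ngram)
    utils::head(sub$ngram[ord], k)
  }
  uni <- pick(sig[sig$n == 1, , drop = FALSE], k_uni)
  bi <- pick(sig[sig$n == 2, , drop = FALSE], k_bi)
  significant <- c(uni, bi)
  list(terms = unique(c(significant, primary_keyword)),
       significant = significant)
}
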