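# Weighted term vectors (TF-IDF), cosine similarity and the pairwise cosine
# similarity score (PCSS).
#
# A vector is a named numeric vector (term -> weight) with no zero entries.
# TF is the raw within-document count; IDF is ln(N / df) over the supplied
# document set, so a term present in every document vanishes.

ngram_tokens <- function(tokens, n_max = 1L) {
  k <- length(tokens)
  if (k == 0L) return(character())
  out <- tokens
  if (n_max >= 2L && k >= 2L) {
    for (n in 2:min(n_max, k)) {
      idx <- seq_len(k - n + 1L)
      grams <- tokens[idx]
      for (j in 1:(n - 1L)) grams <- paste(grams, tokens[idx + j])
      out <- c(out, grams)
    }
  }
  out
}

#' TF-IDF vectors for a set of token lists
#'
#' @param doc_tokens list of character vectors, one per document (already
#'   tokenised, stopword-filtered and, where wanted, stemmed).
#' @param n_max maximum n-gram order included as features (1 = unigrams only).
#' @return list of named numeric vectors (term weights); empty documents give
#'   zero-length vectors.
#' @export
tfidf_vectors <- function(doc_tokens, n_max = 1L) {
  feats <- lapply(doc_tokens, ngram_tokens, n_max = n_max)
  n_docs <- length(feats)
  df <- table(unlist(lapply(feats, unique), use.names = FALSE))
  idf <- log(n_docs / as.numeric(df))
  names(idf) <- names(df)
  lapply(feats, function(f) {
    if (length(f) == 0L) return(stats::setNames(numeric(), character()))
    tf <- table(f)
    w <- as.numeric(tf) * idf[names(tf)]
    w <- stats::setNames(as.numeric(w), names(tf))
    w[w != 0]
  })
}

#' Cosine similarity between two weighted term vectors
#'
#' Cosine with an empty (all-zero) vector is defined as 0.
#'
#' @param a,b named numeric vectors.
#' @return numeric scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) return(0)
  num <- sum(a[shared] * b[shared])
  num / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

pcss_from_cosines <- function(cosines) {
  m <- mean(cosines)
  # population standard deviation: the score is over the complete pair set
  s <- sqrt(mean((cosines - m)^2))
  m - s
}

#' Pairwise cosine similarity score (PCSS)
#'
#' Mean of the cosine similarities over all unordered pairs of vectors, minus
#' the population standard deviation of those similarities. Rewards document
#' sets that are uniformly similar; a set with some strongly related and some
#' unrelated members is penalised through the deviation term.
#'
#' @param vectors list of >= 2 weighted term vectors.
#' @return numeric scalar (at most 1).
#' @export
pcss <- function(vectors) {
  n <- length(vectors)
  if (n < 2L) stop("pcss needs at least two vectors", call. = FALSE)
  cosines <- numeric(n * (n - 1L) / 2L)
  k <- 0L
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      cosines[k] <- cosine_sim(vectors[[i]], vectors[[j]])
    }
  }
  pcss_from_cosines(cosines)
}

#' Cross-set PCSS
#'
#' PCSS over all cross pairs (a, b) with a from `set_a` and b from `set_b`;
#' within-set pairs are excluded. Used for the title-relatedness check between
#' the article sets retrieved by two different search terms.
#'
#' @param set_a,set_b non-empty lists of weighted term vectors.
#' @return numeric scalar (at most 1).
#' @export
cross_pcss <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) {
    stop("cross_pcss needs two non-empty vector sets", call. = FALSE)
  }
  cosines <- numeric(length(set_a) * length(set_b))
  k <- 0L
  for (a in set_a) {
    for (b in set_b) {
      k <- k + 1L
      cosines[k] <- cosine_sim(a, b)
    }
  }
  pcss_from_cosines(cosines)
}

mean_vector <- function(vectors) {
  all_terms <- unique(unlist(lapply(vectors, names), use.names = FALSE))
  if (length(all_terms) == 0L) return(stats::setNames(numeric(), character()))
  acc <- stats::setNames(numeric(length(all_terms)), all_terms)
  for (v in vectors) if (length(v)) acc[names(v)] <- acc[names(v)] + v
  acc <- acc / length(vectors)
  acc[acc != 0]
}
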