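# Standard English stopword list (classic IR list of function words) plus the
# corpus-derived extension used by the term-extraction stage.

#' Standard English stopwords
#'
#' @return character vector of lowercase stopwords.
#' @export
standard_stopwords <- function() {
  c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "you're", "you've", "you'll", "you'd", "your", "yours", "yourself",
    "yourselves", "he", "him", "his", "himself", "she", "she's", "her",
    "hers", "herself", "it", "it's", "its", "itself", "they", "them",
    "their", "theirs", "themselves", "what", "which", "who", "whom",
    "this", "that", "that'll", "these", "those", "am", "is", "are", "was",
    "were", "be", "been", "being", "have", "has", "had", "having", "do",
    "does", "did", "doing", "a", "an", "the", "and", "but", "if", "or",
    "because", "as", "until", "while", "of", "at", "by", "for", "with",
    "about", "against", "between", "into", "through", "during", "before",
    "after", "above", "below", "to", "from", "up", "down", "in", "out",
    "on", "off", "over", "under", "again", "further", "then", "once",
    "here", "there", "when", "where", "why", "how", "all", "any", "both",
    "each", "few", "more", "most", "other", "some", "such", "no", "nor",
    "not", "only", "own", "same", "so", "than", "too", "very", "s", "t",
    "can", "will", "just", "don", "don't", "should", "should've", "now",
    "d", "ll", "m", "o", "re", "ve", "y", "ain", "aren", "aren't",
    "couldn", "couldn't", "didn", "didn't", "doesn", "doesn't", "hadn",
    "hadn't", "hasn", "hasn't", "haven", "haven't", "isn", "isn't", "ma",
    "mightn", "mightn't", "mustn", "mustn't", "needn", "needn't", "shan",
    "shan't", "shouldn", "shouldn't", "wasn", "wasn't", "weren", "weren't",
    "won", "won't", "wouldn", "wouldn't",
    # curly-apostrophe twins, since the tokeniser preserves U+2019
    "you’re", "you’ve", "you’ll", "you’d",
    "she’s", "it’s", "that’ll", "don’t",
    "should’ve", "aren’t", "couldn’t", "didn’t",
    "doesn’t", "hadn’t", "hasn’t", "haven’t",
    "isn’t", "mightn’t", "mustn’t", "needn’t",
    "shan’t", "shouldn’t", "wasn’t", "weren’t",
    "won’t", "wouldn’t", "can’t", "can't", "i'm", "i’m",
    "i've", "i’ve", "i'll", "i’ll", "i'd", "i’d"
  )
}

#' Build the event-level stopword list
#'
#' Union of a standard stopword list and the `top_n` most frequent tokens of
#' the supplied tweet corpus. The frequency cut keeps the whole tie group at
#' the boundary: every token at least as frequent as the `top_n`-th most
#' frequent token is included.
#'
#' @param corpus_texts character vector of tweet texts (or a list of token
#'   vectors, as produced by [tokenize()]).
#' @param standard_list character vector; defaults to [standard_stopwords()].
#' @param top_n number of most frequent corpus tokens to add.
#' @return character vector (a set) of stopwords.
#' @export
build_stopwords <- function(corpus_texts,
                            standard_list = standard_stopwords(),
                            top_n = 200) {
  if (is.list(corpus_texts)) {
    toks <- unlist(corpus_texts, use.names = FALSE)
  } else {
    toks <- unlist(tokenize(corpus_texts), use.names = FALSE)
  }
  extra <- character()
  if (top_n > 0 && length(toks) > 0) {
    freq <- sort(table(toks), decreasing = TRUE)
    if (length(freq) <= top_n) {
      extra <- names(freq)
    } else {
      cut <- as.integer(freq[[top_n]])
      extra <- names(freq)[as.integer(freq) >= cut]
    }
  }
  sort(unique(c(as.character(standard_list), extra)))
}

drop_stopwords <- function(tokens, stopwords) {
  tokens[!(tokens %in% stopwords)]
}
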