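#' Tokenise message text
#'
#' Lowercases, removes URLs and user mentions, strips the hashtag symbol while
#' keeping the tag word, and strips punctuation except intra-word apostrophes.
#' The tokeniser is deterministic and idempotent on its own output.
#'
#' @param text character vector of raw message texts.
#' @return a list (one element per input text) of character vectors of tokens.
#' @examples
#' tokenize("Visit http://x.co @bob NOW!!")  # list(c("visit", "now"))
#' @export
tokenize <- function(text) {
  if (length(text) == 0) return(list())
  t <- tolower(enc2utf8(as.character(text)))
  t[is.na(t)] <- ""
  # URLs and user mentions carry no lexical content for matching
  t <- gsub("(https?://|www\\.)[^[:space:]]+", " ", t, perl = TRUE)
  t <- gsub("(^|[[:space:]])@[[:alnum:]_]+", " ", t, perl = TRUE)
  t <- gsub("#", " ", t, fixed = TRUE)
  # keep letters, digits and apostrophes (straight and curly)
  t <- gsub("[^[:alnum:]'’[:space:]]+", " ", t, perl = TRUE)
  toks <- strsplit(trimws(t), "[[:space:]]+")
  lapply(toks, function(tk) {
    tk <- gsub("^['’]+|['’]+$", "", tk)
    tk[nzchar(tk)]
  })
}

tokenize1 <- function(text) tokenize(text)[[1]]

#' Does a token sequence contain a phrase?
#'
#' Phrases match as consecutive token runs, so "flu" never matches inside
#' "flute" and the two-token alias "throwing up" matches only when the two
#' tokens are adjacent.
#'
#' @param tokens character vector of tokens.
#' @param phrase_tokens character vector, the phrase split into tokens.
#' @return logical scalar.
#' @keywords internal
contains_phrase <- function(tokens, phrase_tokens) {
  np <- length(phrase_tokens)
  nt <- length(tokens)
  if (np == 0L || nt < np) return(FALSE)
  if (np == 1L) return(phrase_tokens %in% tokens)
  hits <- which(tokens == phrase_tokens[[1L]])
  hits <- hits[hits + np - 1L <= nt]
  for (h in hits) {
    if (all(tokens[h:(h + np - 1L)] == phrase_tokens)) return(TRUE)
  }
  FALSE
}
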