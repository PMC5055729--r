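# Keyword groups: a primary keyword naming the group plus alias phrases, per
# event class (symptom / emotion). Tweets are matched to groups by consecutive
# token-phrase matching over the tokenised text.

squish <- function(x) gsub("[[:space:]]+", " ", trimws(tolower(x)))

#' Read a keyword-group configuration
#'
#' The configuration maps event classes to groups to alias lists, in YAML or
#' JSON. All strings are lowercased and whitespace-normalised; duplicate
#' aliases and aliases equal to the primary keyword are dropped. A duplicated
#' primary keyword within an event class is a fatal validation error. With
#' `path = NULL` the packaged defaults (the symptom and emotion groups of the
#' surveillance configuration) are loaded.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration, or `NULL`
#'   for the packaged defaults.
#' @return list of keyword groups, each a list with elements `primary`,
#'   `aliases` and `event_class`.
#' @export
read_keyword_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "keyword_groups.yaml", package = "twevent")
  }
  if (!file.exists(path)) stop("keyword config not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  groups <- list()
  for (cls in names(raw)) {
    cls_norm <- squish(cls)
    if (!cls_norm %in% c("symptom", "emotion")) {
      stop("unknown event class in keyword config: ", cls, call. = FALSE)
    }
    primaries <- squish(names(raw[[cls]]))
    if (anyDuplicated(primaries)) {
      stop("duplicate primary keyword in event class '", cls_norm, "': ",
           paste(primaries[duplicated(primaries)], collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_along(raw[[cls]])) {
      primary <- primaries[[i]]
      if (!nzchar(primary)) stop("empty primary keyword", call. = FALSE)
      aliases <- unlist(raw[[cls]][[i]], use.names = FALSE)
      aliases <- unique(squish(as.character(aliases)))
      aliases <- aliases[nzchar(aliases) & aliases != primary]
      groups[[length(groups) + 1L]] <- list(
        primary = primary, aliases = aliases, event_class = cls_norm)
    }
  }
  names(groups) <- vapply(groups, `[[`, "", "primary")
  groups
}

group_phrases <- function(group) {
  phrases <- c(group$primary, group$aliases)
  lapply(phrases, function(p) strsplit(p, " ", fixed = TRUE)[[1]])
}

#' Add sentiment pseudo-groups to matched-group lists
#'
#' Hook for a pluggable sentiment scorer: tweets scoring at or above
#' `pos_threshold` join the pseudo-group `"very positive"`, those at or below
#' `neg_threshold` join `"very negative"`. The pseudo-groups then flow through
#' aggregation and detection like any keyword group. No sentiment lexicon
#' ships with the package; any function mapping a character vector of texts
#' to numeric scores (e.g. a -5..5 scale) can be used.
#'
#' @param matched list of matched group ids per tweet (from [match_groups()]).
#' @param scores numeric sentiment score per tweet.
#' @param pos_threshold,neg_threshold score cut-offs for the two
#'   pseudo-groups (defaults +-4 on a -5..5 scale).
#' @return the augmented matched list.
#' @export
add_sentiment_groups <- function(matched, scores, pos_threshold = 4,
                                 neg_threshold = -4) {
  stopifnot(length(matched) == length(scores))
  for (i in seq_along(matched)) {
    if (!is.na(scores[i]) && scores[i] >= pos_threshold) {
      matched[[i]] <- c(matched[[i]], "very positive")
    } else if (!is.na(scores[i]) && scores[i] <= neg_threshold) {
      matched[[i]] <- c(matched[[i]], "very negative")
    }
  }
  matched
}

#' Match tweets to keyword groups
#'
#' A tweet matches a group when the group's primary keyword or any alias
#' occurs in the tokenised text; multi-word aliases must occur as consecutive
#' tokens. A tweet matching several aliases of one group yields that group
#' once; a tweet may match several distinct groups.
#'
#' @param texts character vector of tweet texts, or a list of token vectors.
#' @param groups keyword groups from [read_keyword_groups()].
#' @return list (one element per text) of character vectors of matched group
#'   primary keywords.
#' @export
match_groups <- function(texts, groups) {
  toks <- if (is.list(texts)) texts else tokenize(texts)
  phrase_sets <- lapply(groups, group_phrases)
  group_ids <- vapply(groups, `[[`, "", "primary")
  lapply(toks, function(tk) {
    hit <- vapply(phrase_sets, function(ps) {
      any(vapply(ps, contains_phrase, TRUE, tokens = tk))
    }, TRUE)
    unname(group_ids[hit])
  })
}
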