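# Health self-report noise filter: a regularised linear bag-of-words
# classifier separating self-reports of illness ("report") from other keyword
# mentions ("not_report"). The model is a plain term-weight vector plus bias,
# so any externally trained linear predicate can be dropped in via the same
# structure.

bow_matrix <- function(token_lists, vocabulary) {
  i <- integer()
  j <- integer()
  for (d in seq_along(token_lists)) {
    hits <- unique(vocabulary[token_lists[[d]]])
    hits <- hits[!is.na(hits)]
    i <- c(i, rep.int(d, length(hits)))
    j <- c(j, hits)
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(token_lists), length(vocabulary)))
}

#' Train the health-report noise filter
#'
#' Fits a ridge-penalised logistic regression (binomial loss) on binary
#' bag-of-words features over the tokenised texts. The training split is
#' deterministic given `seed`; held-out accuracy on a 20 % split is logged and
#' stored on the model.
#'
#' @param texts character vector of training texts.
#' @param labels character vector, one of `"report"` / `"not_report"` per text.
#' @param seed integer seed controlling the held-out split.
#' @param lambda ridge penalty.
#' @param quiet suppress the training log message.
#' @return an object of class `noise_filter`: `vocabulary` (term -> column
#'   index), `weights`, `bias`, `threshold` (default 0, on the linear score
#'   scale) and `holdout_accuracy`.
#' @export
train_noise_filter <- function(texts, labels, seed = 1L, lambda = 0.01,
                               quiet = FALSE) {
  labels <- as.character(labels)
  if (!all(labels %in% c("report", "not_report"))) {
    stop("labels must be 'report' or 'not_report'", call. = FALSE)
  }
  if (sum(labels == "report") < 2 || sum(labels == "not_report") < 2) {
    stop("need at least two examples of each label", call. = FALSE)
  }
  toks <- tokenize(texts)
  vocab_terms <- sort(unique(unlist(toks, use.names = FALSE)))
  if (length(vocab_terms) < 2) stop("training corpus vocabulary too small",
                                    call. = FALSE)
  vocabulary <- stats::setNames(seq_along(vocab_terms), vocab_terms)
  x <- bow_matrix(toks, vocabulary)
  y <- as.integer(labels == "report")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(y)
  test_idx <- sample.int(n, size = max(1L, floor(0.2 * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  # guard: keep both classes in the training split
  if (length(unique(y[train_idx])) < 2) train_idx <- seq_len(n)

  fit <- glmnet::glmnet(x[train_idx, , drop = FALSE], y[train_idx],
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  weights <- as.numeric(fit$beta[, 1])
  bias <- as.numeric(fit$a0[1])
  scores <- as.numeric(x[test_idx, , drop = FALSE] %*% weights) + bias
  acc <- mean((scores >= 0) == (y[test_idx] == 1L))
  if (!quiet) {
    message(sprintf(
      "train_noise_filter: %d train / %d held-out, held-out accuracy %.3f",
      length(train_idx), length(test_idx), acc))
  }
  structure(list(vocabulary = vocabulary, weights = weights, bias = bias,
                 threshold = 0, holdout_accuracy = acc),
            class = "noise_filter")
}

noise_filter_scores <- function(texts, model) {
  toks <- tokenize(texts)
  vapply(toks, function(tk) {
    idx <- unique(model$vocabulary[tk])
    idx <- idx[!is.na(idx)]
    sum(model$weights[idx]) + model$bias
  }, 0)
}

#' Apply the noise filter to a tweet set
#'
#' With `model = NULL` this is the identity. Otherwise tweets whose linear
#' score is at least `model$threshold` are kept, preserving order.
#'
#' @param tweets tweet data.frame.
#' @param model a `noise_filter` (or compatible list), or `NULL`.
#' @return subset of `tweets`.
#' @export
apply_noise_filter <- function(tweets, model = NULL) {
  if (is.null(model)) return(tweets)
  if (nrow(tweets) == 0) return(tweets)
  keep <- noise_filter_scores(tweets$text, model) >= model$threshold
  out <- tweets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise / deserialise a noise filter as JSON
#'
#' @param model a `noise_filter`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_noise_filter <- function(model, path) {
  payload <- list(vocabulary = as.list(model$vocabulary),
                  weights = model$weights, bias = model$bias,
                  threshold = model$threshold,
                  holdout_accuracy = model$holdout_accuracy)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_noise_filter
#' @export
read_noise_filter <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(
    vocabulary = stats::setNames(as.integer(unlist(payload$vocabulary)),
                                 names(payload$vocabulary)),
    weights = as.numeric(payload$weights),
    bias = as.numeric(payload$bias),
    threshold = as.numeric(payload$threshold),
    holdout_accuracy = as.numeric(payload$holdout_accuracy)
  ), class = "noise_filter")
}
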