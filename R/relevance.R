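#' Weighted-lexicon relevance model
#'
#' A post is "relevant" when it discusses the tracked topic at least
#' partially. The classifier is a weighted lexicon: the score of a post is the
#' sum over lexicon terms of `weight * match_count` in the case-folded,
#' NFC-normalized body, tokenized on non-letter boundaries; a post is labeled
#' relevant when its score reaches `threshold`. With `normalize = TRUE` the
#' score is divided by the post's token count, so long off-topic posts with a
#' stray topic word score lower.
#'
#' Classification is strictly per post, never per thread: forum threads drift
#' off their original topic, so thread-level labels would be unsound.
#'
#' @param terms Named numeric vector (names are lexicon terms, values are
#'   weights), or a two-column data frame `term`, `weight`.
#' @param threshold Finite numeric decision threshold.
#' @param normalize Logical; divide scores by post token count.
#' @return An object of class `lexicon_model`.
#' @examples
#' m <- lexicon_model(c(ccsvi = 1), threshold = 0.5)
#' score_posts("CCSVI is debated", m)
#' @export
lexicon_model <- function(terms, threshold = 0.5, normalize = FALSE) {
  if (is.data.frame(terms)) {
    terms <- setNames(as.numeric(terms$weight), as.character(terms$term))
  }
  if (length(terms) == 0) abort("lexicon must contain at least one term")
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    abort("lexicon terms must be named")
  }
  if (!is.finite(threshold)) abort("threshold must be finite")
  if (any(!is.finite(terms))) abort("lexicon weights must be finite")
  names(terms) <- fold_terms(names(terms))
  structure(
    list(terms = terms, threshold = threshold, normalize = normalize),
    class = "lexicon_model"
  )
}

#' @export
print.lexicon_model <- function(x, ...) {
  cat(
    "<lexicon_model> ", length(x$terms), " terms, threshold ", x$threshold,
    if (x$normalize) ", length-normalized" else "", "\n",
    sep = ""
  )
  invisible(x)
}

fold_terms <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfc(x))
}

# hyperlinks are references, not discussion text: a URL whose domain happens
# to contain a topic word must not make a post "relevant", so bodies are
# stripped of URL substrings before tokenization
tokenize_bodies <- function(body) {
  pat <- "(?i)\\b(?:https?://[^\\s<>\"]+|www\\.[a-z0-9-]+(?:\\.[a-z0-9-]+)+(?:/[^\\s<>\"]*)?)"
  body <- stringr::str_remove_all(body, stringr::regex(pat))
  stringr::str_split(fold_terms(body), "[^\\p{L}]+") |>
    lapply(function(t) t[nzchar(t)])
}

#' Score post bodies against a lexicon
#'
#' @param body Character vector of post bodies.
#' @param model A [lexicon_model()].
#' @return Numeric vector of scores, one per body.
#' @export
score_posts <- function(body, model) {
  stopifnot(inherits(model, "lexicon_model"))
  toks <- tokenize_bodies(body)
  vapply(toks, function(t) {
    if (length(t) == 0) return(0)
    hits <- model$terms[match(t, names(model$terms))]
    s <- sum(hits, na.rm = TRUE)
    if (model$normalize) s / length(t) else s
  }, numeric(1))
}

#' Classify every post of a corpus as relevant or irrelevant
#'
#' @param corpus A [forum_corpus()].
#' @param model A [lexicon_model()].
#' @return Tibble with columns `post_id`, `score`, `relevant` (logical;
#'   `score >= threshold`), one row per corpus post.
#' @export
classify_corpus <- function(corpus, model) {
  stopifnot(inherits(corpus, "forum_corpus"))
  tibble::tibble(
    post_id = corpus$posts$post_id,
    score = score_posts(corpus$posts$body, model),
    relevant = .data$score >= model$threshold
  )
}

#' Train lexicon weights from labeled posts
#'
#' Sets each candidate term's weight to the smoothed log-odds of its document
#' frequency in relevant versus irrelevant posts (additive smoothing 1), and
#' keeps the terms whose weight exceeds `min_weight`. The returned model uses
#' threshold 0 on the unnormalized score, so a post is called relevant when
#' its positive-evidence terms outweigh its negative ones.
#'
#' @param body Character vector of training post bodies.
#' @param relevant Logical vector of gold labels, same length.
#' @param min_weight Keep terms with `abs(weight) > min_weight` (default 0:
#'   drop exactly-neutral terms).
#' @param threshold Decision threshold of the returned model; `NULL`
#'   (default) fits it from the training scores by maximizing training F1
#'   (candidate cuts are the midpoints between adjacent sorted scores).
#' @return A [lexicon_model()].
#' @export
train_lexicon <- function(body, relevant, min_weight = 0, threshold = NULL) {
  stopifnot(length(body) == length(relevant))
  relevant <- as.logical(relevant)
  if (!any(relevant) || all(relevant)) {
    abort("training data needs both relevant and irrelevant posts")
  }
  toks <- tokenize_bodies(body)
  vocab <- unique(unlist(toks))
  df_rel <- table(factor(unlist(lapply(toks[relevant], unique)), levels = vocab))
  df_irr <- table(factor(unlist(lapply(toks[!relevant], unique)), levels = vocab))
  n_rel <- sum(relevant)
  n_irr <- sum(!relevant)
  w <- log((as.numeric(df_rel) + 1) / (n_rel + 2)) -
    log((as.numeric(df_irr) + 1) / (n_irr + 2))
  keep <- abs(w) > min_weight
  model <- lexicon_model(setNames(w[keep], vocab[keep]), threshold = 0)
  if (is.null(threshold)) {
    scores <- score_posts(body, model)
    o <- order(scores)
    s <- scores[o]
    y <- relevant[o]
    # sweeping the cut upward: predicted-positive set shrinks from the top
    tp <- sum(y) - cumsum(y) + y # positives with score >= s[i]
    pp <- n_rel + n_irr - seq_along(s) + 1 # posts with score >= s[i]
    f1 <- 2 * tp / (pp + sum(y))
    i <- which.max(f1)
    threshold <- if (i == 1) s[1] - 1 else (s[i - 1] + s[i]) / 2
  }
  model$threshold <- threshold
  model
}

#' Precision, recall and F1 of relevance predictions
#'
#' Conventions for empty denominators: a 0/0 precision, recall or F1 is
#' returned as `NA` (the undefined marker), never silently coerced to 0 or 1.
#'
#' @param labels Tibble as returned by [classify_corpus()] (columns `post_id`,
#'   `relevant`).
#' @param gold Tibble with columns `post_id`, `relevant` — the reference
#'   labels; its post ids must be a subset of `labels$post_id`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
evaluate_classifier <- function(labels, gold) {
  if (nrow(gold) == 0) abort("gold label set is empty")
  if (!all(gold$post_id %in% labels$post_id)) {
    abort("gold contains post ids absent from labels")
  }
  pred <- labels$relevant[match(gold$post_id, labels$post_id)]
  truth <- gold$relevant
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, recall = recall, f1 = f1
  )
}

#' Read / write a lexicon as two-column TSV
#'
#' @param path Path to a TSV with columns `term`, `weight`.
#' @param threshold,normalize Passed to [lexicon_model()].
#' @return A [lexicon_model()].
#' @export
read_lexicon <- function(path, threshold = 0.5, normalize = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    term = readr::col_character(), weight = readr::col_double()
  ))
  lexicon_model(tab, threshold = threshold, normalize = normalize)
}

#' @rdname read_lexicon
#' @param model A [lexicon_model()] to write.
#' @export
write_lexicon <- function(model, path) {
  stopifnot(inherits(model, "lexicon_model"))
  readr::write_tsv(
    tibble::tibble(term = names(model$terms), weight = unname(model$terms)),
    path
  )
  invisible(path)
}
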