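#' Per-user source-preference vectors
#'
#' Represents every user as a vector in 8-dimensional space: dimension `c`
#' counts the hyperlinks the user posted whose reduced domain falls in source
#' class `c`. Links are de-duplicated within a post (matching the "unique
#' references per post" convention) and, by default, counted in relevant
#' posts only — the clustering this feeds targets users who took part in the
#' on-topic discussion, and eligibility is phrased in relevant hyperlinks.
#' Set `relevant_only = FALSE` to count links in all posts.
#'
#' @param corpus A [forum_corpus()].
#' @param labels Relevance labels from [classify_corpus()].
#' @param map Domain map tibble.
#' @param relevant_only Count links in relevant posts only (default).
#' @param suffixes Public-suffix table.
#' @return Tibble: `user` plus one integer column per class in
#'   [domain_classes()]. Users with no counted links get a zero row.
#' @export
preference_vectors <- function(corpus, labels, map = default_domain_map(),
                               relevant_only = TRUE,
                               suffixes = default_public_suffixes()) {
  stopifnot(inherits(corpus, "forum_corpus"))
  posts <- corpus$posts
  if (relevant_only) {
    keep <- labels$post_id[labels$relevant]
    counted <- posts[posts$post_id %in% keep, , drop = FALSE]
  } else {
    counted <- posts
  }
  links <- counted |>
    dplyr::mutate(urls = lapply(.data$urls, unique)) |>
    dplyr::select(user = "author", "urls") |>
    tidyr::unnest_longer("urls", values_to = "url") |>
    dplyr::filter(!is.na(.data$url)) |>
    dplyr::mutate(
      domain = reduce_url(.data$url, suffixes = suffixes, on_unparseable = "na")
    ) |>
    dplyr::filter(!is.na(.data$domain)) |>
    dplyr::mutate(class = factor(classify_domain(.data$domain, map = map),
                                 levels = domain_classes()))
  all_users <- sort(unique(posts$author))
  wide <- links |>
    dplyr::count(.data$user, .data$class, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  out <- tibble::tibble(user = all_users) |>
    dplyr::left_join(wide, by = "user")
  for (cl in domain_classes()) {
    if (!cl %in% names(out)) out[[cl]] <- 0L
    out[[cl]][is.na(out[[cl]])] <- 0L
  }
  out[c("user", domain_classes())]
}

# body length with references removed: hyperlink substrings are stripped
# before counting; citations are structural (cited_post_ids), not body text
body_length_without_refs <- function(body) {
  pat <- "(?i)\\b(?:https?://[^\\s<>\"]+|www\\.[a-z0-9-]+(?:\\.[a-z0-9-]+)+(?:/[^\\s<>\"]*)?)"
  nchar(stringr::str_remove_all(body, stringr::regex(pat)))
}

# maximal uninterrupted sequences of relevant posts within each thread,
# posts in thread order (timestamp, ties by post_id)
relevant_runs <- function(corpus, labels) {
  posts <- corpus$posts
  posts$relevant <- labels$relevant[match(posts$post_id, labels$post_id)]
  posts |>
    dplyr::group_by(.data$thread_id) |>
    dplyr::mutate(run = cumsum(c(TRUE, diff(.data$relevant) != 0))) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$relevant) |>
    dplyr::group_by(.data$thread_id, .data$run) |>
    dplyr::summarise(authors = list(unique(.data$author)), .groups = "drop")
}

#' The nine per-user contribution-behavior features
#'
#' Computes, for every user over their entire contribution period:
#'
#' * `avg_message_length` — mean body length in characters, hyperlink text
#'   removed (citations are structural and never part of the body).
#' * `posts_per_day` — total posts / (`days_active` + 1); the +1 keeps the
#'   rate defined for single-day users.
#' * `refs_per_post` — mean number of unique hyperlinks per post.
#' * `threads_per_day` — distinct threads contributed to / (`days_active` + 1).
#' * `days_active` — days between first and last post.
#' * `fraction_cited` — share of the user's posts cited at least once by any
#'   post.
#' * `fraction_relevant` — share of the user's posts labeled relevant.
#' * `fraction_initiated` — initiated threads / threads contributed to.
#' * `coverage_per_post` — distinct discussion partners / total posts, where
#'   partners are the other authors co-occurring in the user's relevant runs
#'   (a maximal uninterrupted sequence of relevant posts in one thread is a
#'   single discussion); each partner counts once across all runs, and a
#'   user is never their own partner.
#'
#' @param corpus A [forum_corpus()].
#' @param labels Relevance labels from [classify_corpus()].
#' @return Tibble: `user`, `n_posts`, and the nine feature columns, one row
#'   per user (every user has at least one post by construction).
#' @export
behavior_features <- function(corpus, labels) {
  stopifnot(inherits(corpus, "forum_corpus"))
  posts <- corpus$posts
  posts$relevant <- labels$relevant[match(posts$post_id, labels$post_id)]
  if (anyNA(posts$relevant)) abort("labels do not cover every corpus post")

  cited_ids <- unique(unlist(posts$cited_post_ids))
  th <- threads(corpus)
  initiated_by <- table(th$initiator)

  runs <- relevant_runs(corpus, labels)
  # user -> union of co-authors over the runs the user appears in
  partners_of <- runs |>
    dplyr::mutate(run_id = dplyr::row_number()) |>
    tidyr::unnest_longer("authors", values_to = "member", keep_empty = FALSE) |>
    dplyr::left_join(
      dplyr::mutate(runs, run_id = dplyr::row_number())[c("run_id", "authors")],
      by = "run_id"
    ) |>
    dplyr::group_by(user = .data$member) |>
    dplyr::summarise(
      n_partners = length(setdiff(unique(unlist(.data$authors)), .data$user[1])),
      .groups = "drop"
    )

  feats <- posts |>
    dplyr::mutate(
      body_len = body_length_without_refs(.data$body),
      n_refs = vapply(.data$urls, function(u) length(unique(u)), integer(1)),
      cited = .data$post_id %in% cited_ids
    ) |>
    dplyr::group_by(user = .data$author) |>
    dplyr::summarise(
      n_posts = dplyr::n(),
      avg_message_length = mean(.data$body_len),
      refs_per_post = mean(.data$n_refs),
      days_active = as.numeric(max(.data$timestamp) - min(.data$timestamp)),
      n_threads = dplyr::n_distinct(.data$thread_id),
      fraction_cited = mean(.data$cited),
      fraction_relevant = mean(.data$relevant),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      posts_per_day = .data$n_posts / (.data$days_active + 1),
      threads_per_day = .data$n_threads / (.data$days_active + 1),
      fraction_initiated = as.numeric(initiated_by[.data$user] %||% 0) / .data$n_threads
    ) |>
    dplyr::left_join(partners_of, by = "user") |>
    dplyr::mutate(
      n_partners = dplyr::coalesce(.data$n_partners, 0L),
      coverage_per_post = .data$n_partners / .data$n_posts
    )
  feats$fraction_initiated[is.na(feats$fraction_initiated)] <- 0
  feats[c(
    "user", "n_posts",
    "avg_message_length", "posts_per_day", "refs_per_post", "threads_per_day",
    "days_active", "fraction_cited", "fraction_relevant", "fraction_initiated",
    "coverage_per_post"
  )]
}

#' Names of the nine behavior features
#' @return Character vector, in the column order of [behavior_features()].
#' @export
behavior_feature_names <- function() {
  c(
    "avg_message_length", "posts_per_day", "refs_per_post", "threads_per_day",
    "days_active", "fraction_cited", "fraction_relevant", "fraction_initiated",
    "coverage_per_post"
  )
}

#' Users eligible for clustering
#'
#' Clustering targets users with enough on-topic signal: `mode = "links"`
#' keeps users whose relevant posts contain at least `threshold` hyperlinks
#' (unique within each post); `mode = "posts"` keeps users with at least
#' `threshold` relevant posts. The default threshold is 5 in both modes.
#'
#' @param corpus A [forum_corpus()].
#' @param labels Relevance labels from [classify_corpus()].
#' @param mode `"links"` or `"posts"`.
#' @param threshold Minimum count (>= 1).
#' @return Sorted character vector of eligible user aliases.
#' @export
eligible_users <- function(corpus, labels, mode = c("links", "posts"),
                           threshold = 5) {
  stopifnot(inherits(corpus, "forum_corpus"), threshold >= 1)
  mode <- match.arg(mode)
  posts <- corpus$posts
  rel <- posts[posts$post_id %in% labels$post_id[labels$relevant], , drop = FALSE]
  if (nrow(rel) == 0) return(character())
  tallies <- rel |>
    dplyr::group_by(user = .data$author) |>
    dplyr::summarise(
      n = if (mode == "posts") {
        dplyr::n()
      } else {
        sum(vapply(.data$urls, function(u) length(unique(u)), integer(1)))
      },
      .groups = "drop"
    )
  sort(tallies$user[tallies$n >= threshold])
}

#' Normalize a user-by-feature table
#'
#' `method = "unit"` divides every row by its Euclidean norm, leaving only
#' "taste", not "activity" (rows of all zeros cannot be normalized and abort
#' naming the user). `method = "zscore"` centers every column on its mean
#' and divides by its population standard deviation (a determinism pin —
#' documented, since sample vs population sd is a free choice); constant
#' columns become all-zero with a warning. Both methods are idempotent.
#'
#' @param x Tibble whose first column is `user` and remaining columns are
#'   numeric features (no missing cells).
#' @param method `"unit"` or `"zscore"`.
#' @return `x` normalized, with attribute `normalization` set.
#' @examples
#' normalize_features(tibble::tibble(user = "a", x = 3, y = 4), "unit")
#' @export
normalize_features <- function(x, method = c("unit", "zscore")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(x), names(x)[1] == "user")
  m <- as.matrix(x[-1])
  if (!is.numeric(m) || anyNA(m)) abort("feature columns must be numeric with no missing cells")
  if (method == "unit") {
    norms <- sqrt(rowSums(m^2))
    if (any(norms == 0)) {
      abort(paste0(
        "cannot unit-normalize zero vector(s) for user(s): ",
        paste(utils::head(x$user[norms == 0], 5), collapse = ", ")
      ))
    }
    m <- m / norms
  } else {
    if (nrow(m) < 2) abort("z-score normalization needs at least 2 rows")
    mu <- colMeans(m)
    sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
    const <- sd_pop < 1e-12
    if (any(const)) {
      warn(paste0(
        "constant feature column(s) set to zero: ",
        paste(colnames(m)[const], collapse = ", ")
      ))
      sd_pop[const] <- 1
    }
    m <- sweep(sweep(m, 2, mu), 2, sd_pop, "/")
    m[, const] <- 0
  }
  out <- dplyr::bind_cols(x[1], tibble::as_tibble(m))
  attr(out, "normalization") <- method
  out
}
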