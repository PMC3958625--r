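#' Construct a forum corpus
#'
#' A `forum_corpus` bundles the posts of an online forum (one row per post)
#' with the observation window. Posts carry an opaque `post_id`, the
#' `thread_id` they belong to, the author's alias, a day-resolution
#' `timestamp`, the body text, the ids of any posts they cite, and the
#' hyperlinks they contain. Aliases are taken at face value: the forums this
#' model targets allowed free alias choice, so an alias is treated as a user
#' without any identity resolution.
#'
#' Invariants enforced at construction: `post_id` is unique; every timestamp
#' falls inside `window`; cited posts must exist in the corpus and be no later
#' than the citing post (unknown citation targets are kept but flagged with a
#' warning). If the `urls` column is absent, hyperlinks are extracted from the
#' body with [extract_urls()].
#'
#' @param posts A data frame with columns `post_id`, `thread_id`, `author`,
#'   `timestamp` (`Date` or ISO-8601 string), `body`, and optionally
#'   `cited_post_ids` (list of character vectors) and `urls` (list of
#'   character vectors).
#' @param window Length-2 `Date` (or string) vector, inclusive observation
#'   window. Defaults to the range of the post timestamps.
#' @return An object of class `forum_corpus`: a list with elements `posts`
#'   (tibble, ordered by thread, timestamp, post id), `window`, and
#'   `load_report`.
#' @seealso [read_corpus()], [threads()], [user_index()]
#' @export
forum_corpus <- function(posts, window = NULL) {
  posts <- tibble::as_tibble(posts)
  required <- c("post_id", "thread_id", "author", "timestamp", "body")
  missing_cols <- setdiff(required, names(posts))
  if (length(missing_cols) > 0) {
    abort(paste0("posts is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  posts$post_id <- as.character(posts$post_id)
  posts$thread_id <- as.character(posts$thread_id)
  posts$author <- as.character(posts$author)
  posts$timestamp <- as.Date(posts$timestamp)
  posts$body <- as.character(posts$body)
  if (anyNA(posts$timestamp)) abort("unparseable timestamp in posts")
  if (!"cited_post_ids" %in% names(posts)) {
    posts$cited_post_ids <- rep(list(character()), nrow(posts))
  }
  if (!"urls" %in% names(posts)) {
    hits <- extract_urls(posts$body)
    posts$urls <- if (is.list(hits)) hits else list(hits)
  }
  posts$cited_post_ids <- lapply(posts$cited_post_ids, function(x) {
    if (is.null(x) || length(x) == 0) character() else as.character(x)
  })
  posts$urls <- lapply(posts$urls, function(x) {
    if (is.null(x) || length(x) == 0) character() else as.character(x)
  })

  dup <- posts$post_id[duplicated(posts$post_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate post_id: ", paste(unique(dup), collapse = ", ")))
  }

  if (is.null(window)) {
    window <- range(posts$timestamp)
  }
  window <- as.Date(window)
  if (length(window) != 2 || anyNA(window) || window[1] > window[2]) {
    abort("window must be two ordered dates")
  }
  n_before <- nrow(posts)
  inside <- posts$timestamp >= window[1] & posts$timestamp <= window[2]
  posts <- posts[inside, , drop = FALSE]
  n_dropped <- n_before - nrow(posts)
  if (nrow(posts) == 0) abort("no posts fall inside the window")

  # citation bookkeeping: targets must exist and not postdate the citing post
  cited_all <- unlist(posts$cited_post_ids)
  citing_idx <- rep(seq_len(nrow(posts)), lengths(posts$cited_post_ids))
  pos <- match(cited_all, posts$post_id)
  n_unknown <- sum(is.na(pos))
  bad <- which(!is.na(pos) & posts$timestamp[pos] > posts$timestamp[citing_idx])
  if (length(bad) > 0) {
    abort(paste0(
      "post ", posts$post_id[citing_idx[bad[1]]], " cites later post ",
      cited_all[bad[1]]
    ))
  }
  if (n_unknown > 0) {
    warn(paste0(n_unknown, " citation(s) point to posts outside the corpus (kept, flagged)"))
  }

  posts <- posts[order(posts$thread_id, posts$timestamp, posts$post_id), , drop = FALSE]
  structure(
    list(
      posts = posts,
      window = window,
      load_report = tibble::tibble(
        n_posts = nrow(posts),
        n_threads = dplyr::n_distinct(posts$thread_id),
        n_users = dplyr::n_distinct(posts$author),
        n_dropped_window = n_dropped,
        n_unknown_citations = n_unknown
      )
    ),
    class = "forum_corpus"
  )
}

#' @export
print.forum_corpus <- function(x, ...) {
  r <- x$load_report
  cat(
    "<forum_corpus> ", r$n_posts, " posts / ", r$n_threads, " threads / ",
    r$n_users, " users\n  window ", format(x$window[1]), " .. ",
    format(x$window[2]), "\n",
    sep = ""
  )
  if (r$n_dropped_window > 0) {
    cat("  dropped outside window:", r$n_dropped_window, "\n")
  }
  invisible(x)
}

#' Read a forum corpus from a JSON-lines file
#'
#' The corpus dialect is UTF-8 JSON-lines: one post object per line with
#' fields `post_id`, `thread_id`, `author`, `timestamp` (ISO-8601 date),
#' `body`, and optional arrays `cited_post_ids` and `urls`. Posts dated
#' outside `window` are dropped and counted in the load report.
#'
#' @param path Path to a JSONL corpus file.
#' @param window Optional length-2 date vector; defaults to the full range.
#' @return A [forum_corpus()].
#' @export
read_corpus <- function(path, window = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  recs <- vector("list", length(lines_keep))
  for (j in seq_along(lines_keep)) {
    i <- lines_keep[j]
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) abort(paste0("malformed record at line ", i, ": ", conditionMessage(e)))
    )
    for (f in c("post_id", "thread_id", "author", "timestamp", "body")) {
      if (is.null(rec[[f]])) abort(paste0("malformed record at line ", i, ": missing field '", f, "'"))
    }
    recs[[j]] <- rec
  }
  if (length(recs) == 0) abort("empty corpus file")
  posts <- tibble::tibble(
    post_id = vapply(recs, function(r) as.character(r$post_id), character(1)),
    thread_id = vapply(recs, function(r) as.character(r$thread_id), character(1)),
    author = vapply(recs, function(r) as.character(r$author), character(1)),
    timestamp = vapply(recs, function(r) as.character(r$timestamp), character(1)),
    body = vapply(recs, function(r) as.character(r$body), character(1)),
    cited_post_ids = lapply(recs, function(r) as.character(r$cited_post_ids %||% character())),
    urls = if (any(vapply(recs, function(r) !is.null(r$urls), logical(1)))) {
      lapply(recs, function(r) as.character(r$urls %||% character()))
    } else {
      NULL
    }
  )
  forum_corpus(posts, window = window)
}

#' Write a forum corpus to a JSON-lines file
#'
#' Inverse of [read_corpus()]: emits one JSON object per post with a fixed
#' field order, so that a read/write round trip is record-wise identical.
#'
#' @param corpus A [forum_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "forum_corpus"))
  p <- corpus$posts
  lines <- vapply(seq_len(nrow(p)), function(i) {
    jsonlite::toJSON(
      list(
        post_id = jsonlite::unbox(p$post_id[i]),
        thread_id = jsonlite::unbox(p$thread_id[i]),
        author = jsonlite::unbox(p$author[i]),
        timestamp = jsonlite::unbox(format(p$timestamp[i])),
        body = jsonlite::unbox(p$body[i]),
        cited_post_ids = p$cited_post_ids[[i]],
        urls = p$urls[[i]]
      ),
      auto_unbox = FALSE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Extract hyperlinks from post bodies
#'
#' Finds every maximal substring that looks like a hyperlink: either
#' scheme-prefixed (`http://`, `https://`) or a bare `www.`-prefixed host.
#' Matches are returned in order of appearance and duplicates are preserved —
#' whether repeated identical links in one post count once is a downstream,
#' per-post decision. Trailing sentence punctuation (`.,;:!?`) and a trailing
#' unbalanced `)` are trimmed.
#'
#' @param body Character vector of post bodies.
#' @return If `body` has length 1, a character vector of URLs; otherwise a
#'   list of character vectors, one per body.
#' @examples
#' extract_urls("see http://www.youtube.com/watch?v=a and www.ccsvi.org")
#' @export
extract_urls <- function(body) {
  pat <- "(?i)\\b(?:https?://[^\\s<>\"]+|www\\.[a-z0-9-]+(?:\\.[a-z0-9-]+)+(?:/[^\\s<>\"]*)?)"
  hits <- stringr::str_extract_all(body, stringr::regex(pat))
  hits <- lapply(hits, function(u) {
    u <- stringr::str_remove(u, "[.,;:!?]+$")
    # trim a close-paren only when the URL itself has no matching open paren
    fix <- stringr::str_ends(u, "\\)") & !stringr::str_detect(u, "\\(")
    u[fix] <- stringr::str_remove(u[fix], "\\)+$")
    u
  })
  if (length(body) == 1) hits[[1]] else hits
}

#' Thread table of a corpus
#'
#' One row per thread, with the post ids in deterministic order (timestamp,
#' ties broken by post id) and the initiator — the author of the earliest
#' post under that ordering.
#'
#' @param corpus A [forum_corpus()].
#' @return Tibble with columns `thread_id`, `n_posts`, `post_ids` (list),
#'   `initiator`, `first_date`, `last_date`.
#' @export
threads <- function(corpus) {
  stopifnot(inherits(corpus, "forum_corpus"))
  corpus$posts |>
    dplyr::group_by(.data$thread_id) |>
    dplyr::summarise(
      n_posts = dplyr::n(),
      post_ids = list(.data$post_id),
      initiator = .data$author[1],
      first_date = .data$timestamp[1],
      last_date = .data$timestamp[dplyr::n()],
      .groups = "drop"
    )
}

#' Per-user index of posts and threads
#'
#' Maps every alias appearing in the corpus to its post ids, the threads it
#' contributed to, and the threads it initiated (threads whose earliest post,
#' ties broken by post id, is authored by the alias).
#'
#' @param corpus A [forum_corpus()].
#' @return Tibble with columns `user`, `n_posts`, `post_ids`, `thread_ids`,
#'   `initiated_thread_ids` (the last three are list columns).
#' @export
user_index <- function(corpus) {
  stopifnot(inherits(corpus, "forum_corpus"))
  th <- threads(corpus)
  initiated <- split(th$thread_id, th$initiator)
  corpus$posts |>
    dplyr::group_by(user = .data$author) |>
    dplyr::summarise(
      n_posts = dplyr::n(),
      post_ids = list(.data$post_id),
      thread_ids = list(unique(.data$thread_id)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      initiated_thread_ids = lapply(.data$user, function(u) initiated[[u]] %||% character())
    )
}
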