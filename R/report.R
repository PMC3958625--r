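#' Corpus / sampling flow summary
#'
#' The counts behind the sampling funnel of a role-clustering analysis:
#' corpus size, relevant posts, users, single-post users (online communities
#' show heavy participation inequality — most users post exactly once), and
#' the two eligibility sets (at least `threshold` relevant hyperlinks for the
#' preference clustering; at least `threshold` relevant posts for the
#' behavior clustering) together with their overlap.
#'
#' @param corpus A [forum_corpus()].
#' @param labels Relevance labels from [classify_corpus()].
#' @param threshold Eligibility threshold for both modes (default 5).
#' @return One-row tibble: `n_posts`, `n_threads`, `n_relevant_posts`,
#'   `n_users`, `n_single_post_users`, `single_post_share`,
#'   `n_eligible_links`, `n_eligible_posts`, `n_eligible_overlap`.
#' @export
summarize_flow <- function(corpus, labels, threshold = 5) {
  stopifnot(inherits(corpus, "forum_corpus"))
  posts <- corpus$posts
  per_user <- table(posts$author)
  el_links <- eligible_users(corpus, labels, mode = "links", threshold = threshold)
  el_posts <- eligible_users(corpus, labels, mode = "posts", threshold = threshold)
  tibble::tibble(
    n_posts = nrow(posts),
    n_threads = dplyr::n_distinct(posts$thread_id),
    n_relevant_posts = sum(labels$relevant),
    n_users = length(per_user),
    n_single_post_users = sum(per_user == 1),
    single_post_share = sum(per_user == 1) / length(per_user),
    n_eligible_links = length(el_links),
    n_eligible_posts = length(el_posts),
    n_eligible_overlap = length(intersect(el_links, el_posts))
  )
}

#' Plot the monthly hyperlink timeline by source class
#'
#' @param timeline Tibble from [monthly_domain_counts()].
#' @return A ggplot object (one line per domain class).
#' @export
plot_timeline <- function(timeline) {
  ggplot2::ggplot(
    timeline,
    ggplot2::aes(x = .data$month, y = .data$n, colour = .data$class)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "month", y = "posted hyperlinks", colour = "domain class",
      title = "Posted hyperlinks per month by source class"
    ) +
    ggplot2::theme_minimal()
}

#' Radar chart of a cluster profile
#'
#' One "spoke" per feature; the spoke length is proportional to the cluster's
#' min-max-normalized feature mean (or, for preference profiles, the
#' component of the summed-then-unit-normalized cluster vector). Facets show
#' one chart per cluster.
#'
#' @param profile A `cluster_profile` from [profile_clusters()].
#' @param values `"minmax"` (behavior profiles, default) or `"unit_sums"`
#'   (preference profiles).
#' @return A ggplot object.
#' @export
plot_radar <- function(profile, values = c("minmax", "unit_sums")) {
  values <- match.arg(values)
  stopifnot(inherits(profile, "cluster_profile"))
  tab <- if (values == "minmax") profile$minmax_means else profile$unit_sums
  if (is.null(tab)) abort("profile has no unit_sums; rebuild with unit_sums = TRUE")
  long <- tab |>
    tidyr::pivot_longer(-"cluster", names_to = "feature", values_to = "value") |>
    dplyr::mutate(feature = factor(.data$feature, levels = setdiff(names(tab), "cluster")))
  if (all(long$value == 0)) warn("all-zero profile: radar chart is degenerate")
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$feature, y = .data$value, group = .data$cluster)
  ) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.4, colour = "steelblue") +
    ggplot2::coord_polar() +
    ggplot2::ylim(min(0, min(long$value)), max(1, max(long$value))) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Render a cluster profile to disk (CSV + chart)
#'
#' Charts are views; the CSV backing each chart is the record. The CSV is
#' written deterministically (same profile, byte-identical file); the image
#' bytes may differ across graphics backends.
#'
#' @param profile A `cluster_profile`.
#' @param out_prefix Path prefix; writes `<prefix>.csv` and `<prefix>.png`.
#' @param values Passed to [plot_radar()].
#' @return Invisibly, the paths written.
#' @export
render_radar <- function(profile, out_prefix, values = c("minmax", "unit_sums")) {
  values <- match.arg(values)
  tab <- if (values == "minmax") profile$minmax_means else profile$unit_sums
  if (is.null(tab)) abort("profile has no unit_sums; rebuild with unit_sums = TRUE")
  csv <- paste0(out_prefix, ".csv")
  png <- paste0(out_prefix, ".png")
  readr::write_csv(tab, csv)
  p <- plot_radar(profile, values = values)
  ggplot2::ggsave(png, p, width = 8, height = 6, dpi = 120)
  invisible(c(csv = csv, png = png))
}

#' Publication citation timeline
#'
#' For each catalog publication referenced from the corpus, pairs its
#' publication date with the dates its references were posted, carrying the
#' verification kind (direct, indirect, unverified).
#'
#' @param matches Tibble from [find_reference_matches()] /
#'   [annotate_references()].
#' @param catalog Publication catalog tibble.
#' @param corpus A [forum_corpus()] (supplies post dates).
#' @return Tibble: `pmid`, `title`, `pub_date`, `ref_date`, `kind`.
#' @export
citation_timeline <- function(matches, catalog, corpus) {
  stopifnot(inherits(corpus, "forum_corpus"))
  posts <- corpus$posts
  matches |>
    dplyr::mutate(
      ref_date = posts$timestamp[match(.data$post_id, posts$post_id)],
      title = catalog$title[match(.data$pmid, catalog$pmid)],
      pub_date = catalog$pub_date[match(.data$pmid, catalog$pmid)]
    ) |>
    dplyr::select("pmid", "title", "pub_date", "ref_date", "kind") |>
    dplyr::arrange(.data$pmid, .data$ref_date)
}

#' @rdname citation_timeline
#' @param timeline Output of `citation_timeline()`.
#' @return For `plot_citation_timeline()`: a ggplot object — one row per
#'   publication, publication date marked distinctly from reference dates.
#' @export
plot_citation_timeline <- function(timeline) {
  ggplot2::ggplot(timeline, ggplot2::aes(y = .data$pmid)) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$ref_date, shape = .data$kind),
      colour = "darkgreen", size = 2
    ) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data$pub_date),
      colour = "red", shape = 8, size = 3
    ) +
    ggplot2::labs(x = "date", y = "publication (pmid)", shape = "reference kind") +
    ggplot2::theme_minimal()
}
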