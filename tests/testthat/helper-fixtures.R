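# Fixtures are built in code; no data files.

# A post body of exactly `len` characters once hyperlinks are removed:
# filler letters plus each URL on its own newline (the newline survives
# removal and is counted, so the filler is shortened accordingly).
body_with_urls <- function(len, urls = character()) {
  stopifnot(len > length(urls))
  paste0(
    strrep("a", len - length(urls)),
    paste0(vapply(urls, function(u) paste0("\n", u), character(1)), collapse = "")
  )
}

# 3-post single-thread corpus for loader tests
tiny_posts <- function() {
  tibble::tibble(
    post_id = c("p1", "p2", "p3"),
    thread_id = "t1",
    author = c("ann", "bob", "ann"),
    timestamp = as.Date(c("2010-01-01", "2010-01-02", "2010-01-05")),
    body = c("hello www.ccsvi.org", "reply text", "closing note"),
    cited_post_ids = list(character(), "p1", character()),
    urls = list("www.ccsvi.org", character(), character())
  )
}

# The 12-post / 4-user corpus whose nine behavior features were computed by
# hand (run enumeration for the coverage feature done on paper); the frozen
# expectations live in feature_fixture_expected().
feature_fixture <- function() {
  url_yt <- "http://www.youtube.com/w?v=1"
  url_cc <- "http://ccsvi.org/a"
  url_wiki <- "www.wikipedia.org/wiki/MS"
  url_news <- "http://news1.com/x"
  url_clinic <- "http://clinic1.com/"
  url_org1 <- "http://org1.com/a"
  url_org2 <- "http://org2.com/b"
  posts <- tibble::tibble(
    post_id = sprintf("P%02d", 1:12),
    thread_id = c(rep("T1", 6), rep("T2", 4), "T3", "T3"),
    author = c(
      "ann", "bob", "ann", "cara", "bob", "dan",
      "bob", "dan", "cara", "bob", "cara", "cara"
    ),
    timestamp = as.Date(c(
      "2010-01-01", "2010-01-02", "2010-01-03", "2010-01-04", "2010-01-05",
      "2010-01-06", "2010-01-03", "2010-01-05", "2010-01-07", "2010-01-09",
      "2010-01-06", "2010-01-10"
    )),
    body = c(
      body_with_urls(100, url_yt),
      body_with_urls(50),
      body_with_urls(80, c(url_cc, url_cc)), # same link twice: unique count 1
      body_with_urls(40),
      body_with_urls(60, url_wiki),
      body_with_urls(30),
      body_with_urls(70, url_news),
      body_with_urls(90),
      body_with_urls(20, url_clinic),
      body_with_urls(110),
      body_with_urls(200, c(url_org1, url_org2)),
      body_with_urls(10)
    ),
    cited_post_ids = list(
      character(), "P01", character(), character(), "P03", character(),
      character(), "P07", character(), character(), character(), character()
    )
    # urls column intentionally absent: extracted from the bodies
  )
  forum_corpus(posts, window = as.Date(c("2010-01-01", "2010-12-31")))
}

feature_fixture_labels <- function() {
  tibble::tibble(
    post_id = sprintf("P%02d", 1:12),
    relevant = c(
      TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, # T1: run {P1,P2,P3}, run {P5,P6}
      FALSE, TRUE, TRUE, FALSE, # T2: run {P8,P9}
      TRUE, FALSE # T3: run {P11}
    )
  )
}

# Hand-computed (frozen) Table-style features for the fixture.
feature_fixture_expected <- function() {
  tibble::tribble(
    ~user, ~avg_message_length, ~posts_per_day, ~refs_per_post,
    ~threads_per_day, ~days_active, ~fraction_cited, ~fraction_relevant,
    ~fraction_initiated, ~coverage_per_post,
    "ann", 90, 2 / 3, 1, 1 / 3, 2, 1, 1, 1, 0.5,
    "bob", 72.5, 0.5, 0.5, 0.25, 7, 0.25, 0.5, 0.5, 0.5,
    "cara", 67.5, 4 / 7, 0.75, 3 / 7, 6, 0, 0.5, 1 / 3, 0.25,
    "dan", 60, 1, 0, 1, 1, 0, 1, 0, 1
  )
}

# 100 URLs over 20 registrable domains (including multi-label public
# suffixes), with varying scheme, subdomain, case, port, path and query
url_fixture_100 <- function() {
  domains <- c(
    "example.co.uk", "press.org.uk", "uni.ac.uk", "shop.com.au", "farm.net.au",
    "kiwi.co.nz", "tokyo.co.jp", "rio.com.br", "cape.co.za", "delhi.co.in",
    "youtube.com", "wikipedia.org", "spiegel.de", "clinic.ch", "info1.info",
    "blog.net", "sana.eu", "forum.at", "page.fr", "store.biz"
  )
  prefixes <- c("http://www.", "https://blogs.", "HTTP://A.B.", "https://", "www.")
  suffixes <- c("/watch?v=1", "", ":8080/x", "/deep/dir/file.pdf", "#frag")
  urls <- character(0)
  for (i in seq_along(prefixes)) {
    urls <- c(urls, paste0(prefixes[i], domains, suffixes[i]))
  }
  urls
}

# exhaustive two-cluster partition oracle: minimum SSE over all bipartitions
exhaustive_min_sse <- function(m) {
  n <- nrow(m)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sse <- 0
    for (part in list(m[g, , drop = FALSE], m[!g, , drop = FALSE])) {
      mu <- colMeans(part)
      sse <- sse + sum(sweep(part, 2, mu)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# full pipeline: generate -> classify -> features -> normalize -> k-means,
# returning permutation-matched agreement with the planted archetypes
run_behavior_recovery <- function(seed, n_users = 400) {
  f <- generate_forum(synth_config(seed = seed, n_users = n_users))
  l <- classify_corpus(f$corpus, f$lexicon)
  el <- eligible_users(f$corpus, l, mode = "posts", threshold = 5)
  feats <- behavior_features(f$corpus, l)
  fm <- feats[feats$user %in% el, c("user", behavior_feature_names())]
  z <- normalize_features(fm, "zscore")
  fit <- kmeans_lloyd(z, k = 6, n_restarts = 20, seed = seed)
  planted <- setNames(f$truth$users$archetype, f$truth$users$user)[z$user]
  cbind(match_clusters(planted, fit$assignments), n_eligible = length(el))
}

run_preference_recovery <- function(seed, n_users = 400) {
  f <- generate_forum(synth_config(
    seed = seed, n_users = n_users,
    archetypes = default_preference_archetypes()
  ))
  l <- classify_corpus(f$corpus, f$lexicon)
  el <- eligible_users(f$corpus, l, mode = "links", threshold = 5)
  pv <- preference_vectors(f$corpus, l, map = f$domain_map)
  u <- normalize_features(pv[pv$user %in% el, ], "unit")
  fit <- kmeans_lloyd(u, k = 6, n_restarts = 20, seed = seed)
  planted <- setNames(f$truth$users$archetype, f$truth$users$user)[u$user]
  cbind(match_clusters(planted, fit$assignments), n_eligible = length(el))
}
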