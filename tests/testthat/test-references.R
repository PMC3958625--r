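test_that("reduce_url strips scheme, www, port, path and case", {
  expect_equal(reduce_url("http://www.youtube.com/watch?v=abc"), "youtube.com")
  expect_equal(reduce_url("HTTP://Example.COM:8080"), "example.com")
  # multi-label public suffix per the pinned table
  expect_equal(reduce_url("https://blogs.example.co.uk/x/y.pdf"), "example.co.uk")
  expect_equal(reduce_url("www.uni.ac.uk"), "uni.ac.uk")
  expect_equal(reduce_url("ftp://deep.sub.domain.org/file"), "domain.org")
  expect_equal(reduce_url("http://user:pw@site.de/x"), "site.de")
  expect_error(reduce_url("not a url"), "unparseable")
  expect_equal(reduce_url("::bad::", on_unparseable = "na"), NA_character_)
})

test_that("reduce_url is idempotent on a 100-URL fixture", {
  urls <- url_fixture_100()
  expect_length(urls, 100)
  once <- reduce_url(urls)
  twice <- reduce_url(once)
  expect_equal(twice, once)
  # and reduction only depends on the host, never on path or query
  expect_equal(reduce_url(paste0("http://", once, "/other/path?q=2")), once)
})

test_that("domains classify per the shipped taxonomy with Other fallback", {
  map <- default_domain_map()
  expect_equal(classify_domain("youtube.com", map), "Social")
  expect_equal(classify_domain("wikipedia.org", map), "Scientific")
  expect_equal(classify_domain("zzz-unknown.example", map), "Other")
  expect_error(
    classify_domain("zzz-unknown.example", map, unmapped = "error"),
    "unmapped"
  )
  expect_setequal(unique(map$class) %in% domain_classes(), TRUE)
  expect_length(domain_classes(), 8)
})

test_that("publication catalogs merge citation closure and search, de-duplicated by pmid", {
  seed <- publication_record("100", "seed paper on venous insufficiency")
  cites <- tibble::tibble(citing = c("101", "102"), cited = c("100", "100"))
  search <- dplyr::bind_rows(
    publication_record("102", "follow-up B"),
    publication_record("103", "unrelated search hit")
  )
  cat1 <- suppressWarnings(build_publication_catalog(seed, cites, search))
  expect_equal(cat1$pmid, c("100", "101", "102", "103"))
  expect_equal(nrow(cat1), 4)

  # empty network and search: the seed alone
  expect_equal(build_publication_catalog(seed)$pmid, "100")

  # cyclic citation graphs terminate, each pmid once
  cyc <- tibble::tibble(citing = c("100", "101", "102"), cited = c("101", "102", "100"))
  cat2 <- suppressWarnings(build_publication_catalog(seed, cyc))
  expect_equal(cat2$pmid, c("100", "101", "102"))

  # order independence
  cat3 <- suppressWarnings(build_publication_catalog(seed, cites[2:1, ], search[2:1, ]))
  expect_equal(cat3$pmid, cat1$pmid)

  # records without pmid are rejected with a warning
  bad <- search
  bad$pmid[1] <- NA
  expect_warning(build_publication_catalog(seed, NULL, bad), "without a pmid")
})

test_that("publication matching uses title substrings and identifier hits, not word bags", {
  catalog <- dplyr::bind_rows(
    publication_record("19060024", "Chronic cerebrospinal venous insufficiency in patients",
                       alt_ids = "10.1136/jnnp.2008.157164"),
    publication_record("777", "A totally different title")
  )
  expect_equal(
    match_publications(
      "they cite Chronic  Cerebrospinal venous INSUFFICIENCY in patients today",
      catalog
    ),
    "19060024"
  )
  expect_equal(match_publications("see PMID: 19060024 for details", catalog), "19060024")
  expect_equal(match_publications("doi:10.1136/JNNP.2008.157164", catalog), "19060024")
  # a shared single word is not a match, nor is the pmid inside a longer number
  expect_length(match_publications("venous problems are different", catalog), 0)
  expect_length(match_publications("order number 919060024999", catalog), 0)
})

test_that("reference detection walks the offline document store and stays unverified", {
  dir <- withr::local_tempdir()
  writeLines("this page quotes the seed title: venous insufficiency explained",
             file.path(dir, "doc1.txt"))
  writeLines("unrelated content", file.path(dir, "doc2.txt"))
  readr::write_tsv(
    tibble::tibble(
      url = c("http://blog.example.com/a", "http://other.org/b"),
      file = c("doc1.txt", "doc2.txt")
    ),
    file.path(dir, "index.tsv")
  )
  store <- read_document_store(dir)
  expect_equal(nrow(store), 2)

  posts <- tiny_posts()
  posts$urls <- list("http://blog.example.com/a", "http://other.org/b", character())
  corpus <- forum_corpus(posts)
  catalog <- publication_record("42", "venous insufficiency explained")
  matches <- find_reference_matches(corpus, catalog, store)
  expect_equal(matches$post_id, "p1")
  expect_equal(matches$kind, "unverified")

  ann <- annotate_references(
    matches,
    tibble::tibble(url = "http://blog.example.com/a", pmid = "42", kind = "indirect")
  )
  expect_equal(ann$kind, "indirect")
  expect_error(
    annotate_references(matches, tibble::tibble(url = "u", pmid = "42", kind = "maybe")),
    "unknown annotation kind"
  )
})

test_that("monthly domain counts: scope difference equals the links in irrelevant posts", {
  posts <- tibble::tibble(
    post_id = sprintf("p%d", 1:6),
    thread_id = "t1",
    author = c("a", "b", "a", "b", "a", "b"),
    timestamp = as.Date(c(rep("2010-03-05", 4), "2010-04-02", "2010-04-03")),
    body = "text",
    urls = list(
      c("http://youtube.com/1", "http://facebook.com/2"), # relevant: 2 Social
      "http://spiegel.de/x", # irrelevant: 1 News
      character(), # relevant
      c("http://youtube.com/9", "http://youtube.com/9"), # irrelevant: dup -> 1
      "http://wikipedia.org/w", # relevant: 1 Scientific
      character() # irrelevant
    )
  )
  corpus <- forum_corpus(posts, window = as.Date(c("2010-03-01", "2010-04-30")))
  labels <- tibble::tibble(
    post_id = posts$post_id,
    relevant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  rel <- monthly_domain_counts(corpus, labels, scope = "relevant_only")
  all <- monthly_domain_counts(corpus, labels, scope = "all")
  # hand count: relevant links 3 (2 Social in March, 1 Scientific in April)
  expect_equal(sum(rel$n), 3)
  expect_equal(rel$n[rel$month == as.Date("2010-03-01") & rel$class == "Social"], 2L)
  expect_equal(rel$n[rel$month == as.Date("2010-04-01") & rel$class == "Scientific"], 1L)
  # the two scopes differ by exactly the links in irrelevant posts (2)
  expect_equal(sum(all$n) - sum(rel$n), 2)
  # zero months/classes are present, grid covers window x 8 classes
  expect_equal(nrow(rel), 2 * 8)
})

test_that("domain-count conservation holds on generated corpora", {
  f <- generate_forum(synth_config(seed = 9, n_users = 80))
  labels <- classify_corpus(f$corpus, f$lexicon)
  tab <- monthly_domain_counts(f$corpus, labels, map = f$domain_map, scope = "all")
  counted <- sum(vapply(
    f$corpus$posts$urls, function(u) length(unique(u)), integer(1)
  ))
  expect_equal(sum(tab$n), counted)
})
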