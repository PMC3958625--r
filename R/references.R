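#' The eight information-source domain classes
#'
#' Hyperlinked sources are grouped by the registrable domain of the URL into
#' a closed taxonomy of eight classes: `Organization` (foundations,
#' associations, unions), `Commerce` (businesses not selling treatment),
#' `News` (commercial news providers), `Other`, `Personal` (static content
#' from a single person), `Scientific` (scientific work and knowledge,
#' including the online encyclopedia), `Social` (social media built on
#' user-generated content), and `HealthcareProviders` (doctors' offices,
#' clinics, professional Q&A).
#'
#' @return Character vector of the 8 class names, in canonical order.
#' @export
domain_classes <- function() {
  c(
    "Organization", "Commerce", "News", "Other",
    "Personal", "Scientific", "Social", "HealthcareProviders"
  )
}

#' Pinned public-suffix table
#'
#' @return Character vector of public suffixes (an offline snapshot shipped
#'   with the package; extend by passing your own table to [reduce_url()]).
#' @export
default_public_suffixes <- function() {
  path <- system.file("extdata", "public_suffixes.txt", package = "forumminer")
  x <- readLines(path, encoding = "UTF-8")
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Reduce URLs to their registrable ("basic") domain
#'
#' Everything but the domain name is discarded: scheme, credentials, port,
#' path, query, fragment, and any subdomain labels below the registrable
#' domain (one label plus the longest matching public suffix). The result is
#' lower-cased, so reduction is idempotent: `reduce_url(reduce_url(u))`
#' equals `reduce_url(u)`.
#'
#' Hosts whose suffix is not in the table fall back to the last label as the
#' suffix; all-numeric hosts (IP addresses) are returned unchanged.
#'
#' @param url Character vector of URLs or bare hosts.
#' @param suffixes Public-suffix table; defaults to the pinned snapshot.
#' @param on_unparseable `"error"` (default) aborts naming the offending raw
#'   strings; `"na"` returns `NA` for them so callers can build a reject
#'   report.
#' @return Character vector of registrable domains.
#' @examples
#' reduce_url("http://www.youtube.com/watch?v=abc")
#' reduce_url("https://blogs.example.co.uk/x/y.pdf")
#' @export
reduce_url <- function(url, suffixes = default_public_suffixes(),
                       on_unparseable = c("error", "na")) {
  on_unparseable <- match.arg(on_unparseable)
  host <- trimws(url)
  host <- stringr::str_remove(host, "^[A-Za-z][A-Za-z0-9+.-]*://")
  host <- stringr::str_remove(host, "^[^/?#@]*@")
  host <- stringr::str_remove(host, "[/?#].*$")
  host <- stringr::str_remove(host, ":\\d*$")
  host <- tolower(stringr::str_remove(host, "\\.+$"))
  ok <- stringr::str_detect(host, "^[a-z0-9-]+(\\.[a-z0-9-]+)+$")
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    if (on_unparseable == "error") {
      abort(paste0(
        "unparseable URL(s): ",
        paste(utils::head(url[!ok], 5), collapse = ", ")
      ))
    }
  }
  suffix_set <- tolower(suffixes)
  out <- rep(NA_character_, length(host))
  for (i in which(ok)) {
    labels <- strsplit(host[i], ".", fixed = TRUE)[[1]]
    if (all(stringr::str_detect(labels, "^\\d+$"))) {
      out[i] <- host[i] # IP literal: nothing to reduce
      next
    }
    n <- length(labels)
    suffix_len <- 1L
    for (len in seq_len(n - 1L)) {
      cand <- paste(labels[(n - len + 1L):n], collapse = ".")
      if (cand %in% suffix_set) suffix_len <- len
    }
    if (suffix_len >= n) {
      # the host is itself a public suffix: no registrable part
      if (on_unparseable == "error") {
        abort(paste0("URL has no registrable domain: ", url[i]))
      }
      next
    }
    out[i] <- paste(labels[(n - suffix_len):n], collapse = ".")
  }
  out
}

#' Read a domain-classification map
#'
#' @param path TSV with columns `domain` (registrable domains) and `class`
#'   (one of [domain_classes()]).
#' @return Tibble with columns `domain`, `class`.
#' @export
read_domain_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(
    domain = readr::col_character(), class = readr::col_character()
  ))
  bad <- setdiff(unique(map$class), domain_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown domain class(es) in map: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(map$domain)) abort("duplicate domains in map")
  map
}

#' Domain map shipped with the package
#'
#' Covers the domains named in the source taxonomy (video sharing, social
#' networks, the online encyclopedia) plus a few per-class exemplars; extend
#' it with your own TSV via [read_domain_map()] and `dplyr::bind_rows()`.
#'
#' @return Tibble with columns `domain`, `class`.
#' @export
default_domain_map <- function() {
  read_domain_map(system.file("extdata", "domain_map.tsv", package = "forumminer"))
}

#' Classify registrable domains into the 8 source classes
#'
#' @param domain Character vector of already-reduced domains (see
#'   [reduce_url()]).
#' @param map Domain map tibble (`domain`, `class`).
#' @param unmapped `"other"` (default): unmapped domains fall back to the
#'   `Other` class; `"error"`: abort naming the first unmapped domains.
#' @return Character vector of class names.
#' @export
classify_domain <- function(domain, map = default_domain_map(),
                            unmapped = c("other", "error")) {
  unmapped <- match.arg(unmapped)
  cls <- map$class[match(tolower(domain), tolower(map$domain))]
  if (anyNA(cls)) {
    if (unmapped == "error") {
      abort(paste0(
        "unmapped domain(s): ",
        paste(utils::head(unique(domain[is.na(cls)]), 5), collapse = ", ")
      ))
    }
    cls[is.na(cls)] <- "Other"
  }
  cls
}

#' Construct a publication record
#'
#' @param pmid Publication identifier (coerced to character).
#' @param title Publication title (may be `NA` for stub records known only
#'   from citation edges).
#' @param alt_ids Character vector of alternative identifiers (DOI etc.).
#' @param pub_date Publication date (`Date` or string), or `NA`.
#' @param annotation Optional free-text annotation (e.g. stance).
#' @return One-row tibble.
#' @export
publication_record <- function(pmid, title = NA_character_,
                               alt_ids = character(), pub_date = NA,
                               annotation = NA_character_) {
  if (is.null(pmid) || is.na(pmid) || !nzchar(as.character(pmid))) {
    abort("publication record requires a pmid")
  }
  tibble::tibble(
    pmid = as.character(pmid),
    title = as.character(title),
    alt_ids = list(as.character(alt_ids)),
    pub_date = as.Date(pub_date),
    annotation = as.character(annotation)
  )
}

#' Build a de-duplicated publication catalog
#'
#' Merges (1) the citation network grown from a seed publication — every
#' pmid reachable from the seed along citation edges, up to `max_depth`
#' hops — with (2) a list of keyword-search results, removing duplicates by
#' pmid. Network pmids without a full record become stub rows (`title = NA`)
#' with a warning; records lacking a pmid are rejected with a warning. The
#' catalog is returned in deterministic pmid order, so construction is
#' independent of input order.
#'
#' @param seed A [publication_record()] (one-row tibble) to grow the
#'   citation network from.
#' @param citation_records Data frame with columns `citing`, `cited`
#'   (pmids), or `NULL`.
#' @param search_results Tibble of [publication_record()] rows, or `NULL`.
#' @param records Optional tibble of records for pmids appearing in the
#'   citation network.
#' @param max_depth Traversal depth; `Inf` (default) takes the full closure.
#' @return Catalog tibble (columns as [publication_record()]).
#' @export
build_publication_catalog <- function(seed, citation_records = NULL,
                                      search_results = NULL, records = NULL,
                                      max_depth = Inf) {
  stopifnot(is.data.frame(seed), nrow(seed) == 1)
  pool <- dplyr::bind_rows(seed, records, search_results)
  no_pmid <- is.na(pool$pmid) | !nzchar(pool$pmid)
  if (any(no_pmid)) {
    warn(paste0("rejected ", sum(no_pmid), " record(s) without a pmid"))
    pool <- pool[!no_pmid, , drop = FALSE]
  }

  reached <- seed$pmid
  if (!is.null(citation_records) && nrow(citation_records) > 0) {
    edges <- dplyr::mutate(
      citation_records,
      citing = as.character(.data$citing), cited = as.character(.data$cited)
    )
    frontier <- reached
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- unique(c(
        edges$citing[edges$cited %in% frontier],
        edges$cited[edges$citing %in% frontier]
      ))
      frontier <- setdiff(nxt, reached)
      reached <- c(reached, frontier)
      depth <- depth + 1
    }
  }

  search_pmids <- as.character(search_results$pmid)
  search_pmids <- search_pmids[!is.na(search_pmids) & nzchar(search_pmids)]
  keep_pmids <- unique(c(reached, search_pmids))
  known <- unique(pool$pmid)
  stubs <- setdiff(keep_pmids, known)
  if (length(stubs) > 0) {
    warn(paste0(
      length(stubs), " citation-network pmid(s) lack full records; added as stubs"
    ))
    pool <- dplyr::bind_rows(
      pool,
      purrr::map_dfr(stubs, function(p) publication_record(p))
    )
  }
  pool |>
    dplyr::filter(.data$pmid %in% keep_pmids) |>
    dplyr::distinct(.data$pmid, .keep_all = TRUE) |>
    dplyr::arrange(.data$pmid)
}

normalize_match_text <- function(x) {
  stringr::str_squish(tolower(stringi::stri_trans_nfc(x)))
}

#' Find catalog publications referenced in a document
#'
#' A publication matches when its whitespace-normalized, case-folded title
#' occurs as a substring of the (equally normalized) document text, or when
#' any of its identifiers occurs: pmids are matched as standalone digit runs
#' (never inside a longer number), alternative ids as case-insensitive
#' substrings. Matches found this way are unverified until a human annotates
#' them as direct or indirect references.
#'
#' @param text Document text (single string).
#' @param catalog Catalog tibble from [build_publication_catalog()].
#' @return Character vector of matching pmids (catalog order).
#' @export
match_publications <- function(text, catalog) {
  ntext <- normalize_match_text(text)
  pmid_hits <- stringr::str_extract_all(ntext, "(?<!\\d)\\d+(?!\\d)")[[1]]
  hit <- vapply(seq_len(nrow(catalog)), function(i) {
    if (catalog$pmid[i] %in% pmid_hits) return(TRUE)
    title <- catalog$title[i]
    if (!is.na(title) && nzchar(title) &&
        stringr::str_detect(ntext, stringr::fixed(normalize_match_text(title)))) {
      return(TRUE)
    }
    alts <- catalog$alt_ids[[i]]
    length(alts) > 0 && any(stringr::str_detect(
      ntext, stringr::fixed(normalize_match_text(alts))
    ))
  }, logical(1))
  catalog$pmid[hit]
}

#' Read an offline document store
#'
#' A document store replaces live fetching of linked webpages/PDF text: a
#' directory containing an `index.tsv` (columns `url`, `file`) and one text
#' file per fetched URL.
#'
#' @param dir Directory path.
#' @return Tibble with columns `url`, `text`.
#' @export
read_document_store <- function(dir) {
  idx <- readr::read_tsv(file.path(dir, "index.tsv"), col_types = readr::cols(
    url = readr::col_character(), file = readr::col_character()
  ))
  idx$text <- vapply(
    idx$file,
    function(f) paste(readLines(file.path(dir, f), encoding = "UTF-8", warn = FALSE), collapse = "\n"),
    character(1)
  )
  idx[c("url", "text")]
}

#' Detect publication references behind posted hyperlinks
#'
#' For every hyperlink posted to the corpus (including links in irrelevant
#' posts), looks the URL up in the offline document store and searches the
#' stored text for catalog publications. Every match is emitted with
#' `kind = "unverified"`; use [annotate_references()] to upgrade matches to
#' direct or indirect after human verification.
#'
#' @param corpus A [forum_corpus()].
#' @param catalog Publication catalog tibble.
#' @param doc_store Tibble from [read_document_store()] (columns `url`,
#'   `text`).
#' @return Tibble with columns `post_id`, `url`, `pmid`, `kind`.
#' @export
find_reference_matches <- function(corpus, catalog, doc_store) {
  stopifnot(inherits(corpus, "forum_corpus"))
  links <- corpus$posts |>
    dplyr::select("post_id", "urls") |>
    tidyr::unnest_longer("urls", values_to = "url") |>
    dplyr::filter(!is.na(.data$url)) |>
    dplyr::distinct(.data$post_id, .data$url)
  links$text <- doc_store$text[match(links$url, doc_store$url)]
  links |>
    dplyr::filter(!is.na(.data$text)) |>
    dplyr::mutate(pmid = purrr::map(.data$text, match_publications, catalog = catalog)) |>
    dplyr::select("post_id", "url", "pmid") |>
    tidyr::unnest_longer("pmid") |>
    dplyr::filter(!is.na(.data$pmid)) |>
    dplyr::mutate(kind = "unverified")
}

#' Apply human verification annotations to reference matches
#'
#' @param matches Tibble from [find_reference_matches()].
#' @param annotations Tibble with columns `url`, `pmid`, `kind` where `kind`
#'   is `"direct"` (a link to the publication itself), `"indirect"` (a
#'   resource solely discussing the publication), or `"reject"` (drop the
#'   match).
#' @return `matches` with `kind` upgraded; rejected rows removed.
#' @export
annotate_references <- function(matches, annotations) {
  bad <- setdiff(unique(annotations$kind), c("direct", "indirect", "reject"))
  if (length(bad) > 0) {
    abort(paste0("unknown annotation kind(s): ", paste(bad, collapse = ", ")))
  }
  key <- paste(matches$url, matches$pmid)
  akey <- paste(annotations$url, annotations$pmid)
  kind <- annotations$kind[match(key, akey)]
  matches$kind <- dplyr::coalesce(kind, matches$kind)
  matches[matches$kind != "reject", , drop = FALSE]
}

#' Monthly hyperlink counts by domain class
#'
#' Each posted hyperlink (duplicates within one post collapsed; duplicates
#' across posts counted each time) contributes one count to the calendar
#' month of its post and the source class of its reduced domain. The table
#' covers every month of the corpus window, zero-filled, with all 8 classes
#' present.
#'
#' @param corpus A [forum_corpus()].
#' @param labels Relevance labels from [classify_corpus()]; required for
#'   `scope = "relevant_only"`.
#' @param map Domain map tibble.
#' @param scope Count links in relevant posts only, or in all posts.
#' @param suffixes Public-suffix table for [reduce_url()].
#' @return Tibble with columns `month` (first day of month), `class`, `n`.
#' @export
monthly_domain_counts <- function(corpus, labels = NULL,
                                  map = default_domain_map(),
                                  scope = c("relevant_only", "all"),
                                  suffixes = default_public_suffixes()) {
  stopifnot(inherits(corpus, "forum_corpus"))
  scope <- match.arg(scope)
  posts <- corpus$posts
  if (scope == "relevant_only") {
    if (is.null(labels)) abort("labels are required for scope = 'relevant_only'")
    keep <- labels$post_id[labels$relevant]
    posts <- posts[posts$post_id %in% keep, , drop = FALSE]
  }
  links <- posts |>
    dplyr::mutate(urls = lapply(.data$urls, unique)) |>
    dplyr::select("post_id", "timestamp", "urls") |>
    tidyr::unnest_longer("urls", values_to = "url") |>
    dplyr::filter(!is.na(.data$url))
  months <- seq(
    as.Date(format(corpus$window[1], "%Y-%m-01")),
    as.Date(format(corpus$window[2], "%Y-%m-01")),
    by = "month"
  )
  grid <- tidyr::expand_grid(month = months, class = domain_classes())
  if (nrow(links) == 0) {
    return(dplyr::mutate(grid, n = 0L))
  }
  links |>
    dplyr::mutate(
      domain = reduce_url(.data$url, suffixes = suffixes, on_unparseable = "na"),
      class = classify_domain(.data$domain, map = map),
      month = as.Date(format(.data$timestamp, "%Y-%m-01"))
    ) |>
    dplyr::filter(!is.na(.data$domain)) |>
    dplyr::count(.data$month, .data$class) |>
    dplyr::right_join(grid, by = c("month", "class")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::arrange(.data$month, match(.data$class, domain_classes()))
}
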