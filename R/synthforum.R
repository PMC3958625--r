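#' Define a user archetype for the synthetic forum
#'
#' An archetype is a planted behavioral/source-preference profile: how often
#' its users post, for how long they stay, how often they start threads, how
#' on-topic they are, how many hyperlinks they include, how long their posts
#' are, and which source classes their links come from. The generator plants
#' these profiles so that the feature and clustering stages can be validated
#' against known ground truth.
#'
#' @param name Archetype name.
#' @param weight Population share among multi-post users.
#' @param posts_per_day_mean Mean posting rate (posts per active day; the
#'   per-user post count is Poisson with mean `rate * (days_active + 1)`).
#' @param days_active_range Integer range (min, max) of the span between a
#'   user's first and last post, in days.
#' @param initiation_prob Probability a post starts a new thread.
#' @param relevance_prob Probability an author-driven post is on-topic.
#' @param refs_per_post_mean Mean hyperlinks per post (Poisson).
#' @param body_length_mean Mean body length in characters (before links).
#' @param preference_distribution Named probability vector over
#'   [domain_classes()] (must sum to 1) governing link emission.
#' @return One-row tibble (list columns for the range and the preference).
#' @export
archetype_spec <- function(name, weight, posts_per_day_mean, days_active_range,
                           initiation_prob, relevance_prob, refs_per_post_mean,
                           body_length_mean, preference_distribution) {
  probs <- c(initiation_prob, relevance_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (length(days_active_range) != 2 || days_active_range[1] > days_active_range[2] ||
      days_active_range[1] < 0) {
    abort("days_active_range must be an ordered non-negative pair")
  }
  pd <- preference_distribution[domain_classes()]
  if (anyNA(pd) || abs(sum(pd) - 1) > 1e-8) {
    abort("preference_distribution must cover all 8 classes and sum to 1")
  }
  tibble::tibble(
    name = name, weight = weight,
    posts_per_day_mean = posts_per_day_mean,
    days_active_range = list(as.integer(days_active_range)),
    initiation_prob = initiation_prob,
    relevance_prob = relevance_prob,
    refs_per_post_mean = refs_per_post_mean,
    body_length_mean = body_length_mean,
    preference_distribution = list(pd)
  )
}

pref_concentrated <- function(class, mass = 0.8) {
  p <- rep((1 - mass) / 7, 8)
  names(p) <- domain_classes()
  p[class] <- mass
  p
}

pref_uniform <- function() {
  setNames(rep(1 / 8, 8), domain_classes())
}

#' Default behavior archetypes
#'
#' Six roles around an "average" baseline, mirroring the named roles of
#' forum-role studies in relative terms: a focused responder (rarely
#' initiates, almost exclusively on-topic, long membership), a highly active
#' relational poster (about 4 posts per day, rarely initiates), an activator
#' (initiates often, on-topic, ~3x the references of the average user), a
#' sophisticated contributor (posts ~3x as long as average with ~5x the
#' references), and a short-lived spammer (active for a few days only, many
#' short on-topic posts, few references). Absolute baselines are free
#' parameters of the generator, not claims about any real forum; the weights
#' keep the average role largest and the sophisticated/spammer roles
#' smallest while giving every role enough members for recovery testing.
#'
#' @return Tibble of [archetype_spec()] rows.
#' @export
default_behavior_archetypes <- function() {
  dplyr::bind_rows(
    archetype_spec("average", 0.40, 0.5, c(100, 160), 0.10, 0.45, 0.8, 300,
                   pref_uniform()),
    archetype_spec("focused_responder", 0.18, 0.15, c(200, 300), 0.02, 0.90, 0.8, 300,
                   pref_uniform()),
    archetype_spec("highly_active_relational", 0.10, 4.0, c(100, 160), 0.05, 0.45, 0.8, 250,
                   pref_uniform()),
    archetype_spec("activator", 0.12, 0.6, c(100, 160), 0.60, 0.90, 2.4, 350,
                   pref_concentrated("Organization")),
    archetype_spec("sophisticated", 0.10, 0.4, c(200, 300), 0.10, 0.60, 4.0, 900,
                   pref_concentrated("Scientific")),
    archetype_spec("spammer", 0.10, 3.0, c(2, 4), 0.30, 0.95, 0.2, 120,
                   pref_uniform())
  )
}

#' Default source-preference archetypes
#'
#' Six roles that share a common posting baseline but differ in where their
#' hyperlinks point: social-media fans, organization followers, balanced
#' source users (uniform over all 8 classes), homepage promoters (personal
#' sites), seekers of healthcare, and users of uncommon sources (the
#' residual class). Used to validate the unit-vector preference clustering.
#'
#' @return Tibble of [archetype_spec()] rows.
#' @export
default_preference_archetypes <- function() {
  base <- function(name, pref) {
    archetype_spec(name, 1 / 6, 0.5, c(100, 160), 0.10, 0.80, 2.0, 300, pref)
  }
  dplyr::bind_rows(
    base("social_media_fan", pref_concentrated("Social")),
    base("organization_follower", pref_concentrated("Organization")),
    base("balanced_source_user", pref_uniform()),
    base("homepage_promoter", pref_concentrated("Personal")),
    base("healthcare_seeker", pref_concentrated("HealthcareProviders")),
    base("uncommon_source_user", pref_concentrated("Other"))
  )
}

#' Synthetic forum configuration
#'
#' @param n_users Number of users to generate.
#' @param window Length-2 date vector, the corpus window.
#' @param single_post_share Probability a user posts exactly once (heavy
#'   participation inequality is the norm in online communities; the classic
#'   observation is that nearly two-thirds of users post only once).
#' @param topic_drift_prob Probability that a non-initiating post redraws
#'   the thread's relevance state from its author (instead of continuing the
#'   thread's current state). 0 keeps every thread uniformly on- or
#'   off-topic; 1 makes relevance fully author-driven.
#' @param cite_prob Probability a non-initiating post cites an earlier post
#'   of its thread.
#' @param join_window Days a thread stays joinable after its last post.
#' @param ambiguity_prob Probability a relevant post omits its topic tokens,
#'   making it invisible to the lexicon classifier (default 0: the planted
#'   lexicon is then a perfect oracle).
#' @param archetypes Tibble of [archetype_spec()] rows; weights must sum
#'   to 1.
#' @param seed Integer seed; the same config and seed yield a byte-identical
#'   corpus.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_users = 400,
                         window = as.Date(c("2008-01-01", "2012-08-17")),
                         single_post_share = 0.65,
                         topic_drift_prob = 0.7,
                         cite_prob = 0.25,
                         join_window = 14,
                         ambiguity_prob = 0,
                         archetypes = default_behavior_archetypes(),
                         seed = 1) {
  window <- as.Date(window)
  if (abs(sum(archetypes$weight) - 1) > 1e-8) {
    abort("archetype weights must sum to 1")
  }
  probs <- c(single_post_share, topic_drift_prob, cite_prob, ambiguity_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_users < 1) abort("n_users must be positive")
  max_days <- max(vapply(archetypes$days_active_range, max, integer(1)))
  if (max_days >= as.numeric(window[2] - window[1])) {
    abort("window too short for the archetypes' activity spans")
  }
  structure(
    list(
      n_users = as.integer(n_users), window = window,
      single_post_share = single_post_share,
      topic_drift_prob = topic_drift_prob,
      cite_prob = cite_prob, join_window = join_window,
      ambiguity_prob = ambiguity_prob,
      archetypes = archetypes, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

synth_topic_terms <- function() {
  c("ccsvi", "zamboni", "venenverengung", "liberation", "stenose", "venoplastie")
}

synth_background_vocab <- function() {
  # disjoint from the topic terms by construction
  c(
    "heute", "wieder", "gelesen", "meinung", "therapie", "termin", "arzt",
    "frage", "antwort", "danke", "gruss", "forum", "beitrag", "woche",
    "symptome", "schub", "medikament", "erfahrung", "bericht", "leben",
    "familie", "arbeit", "hoffnung", "studie", "gestern", "morgen", "zeit",
    "immer", "vielleicht", "eigentlich", "wirklich", "problem", "hilfe"
  )
}

synth_domain_pool <- function() {
  tibble::tribble(
    ~domain, ~class,
    "youtube.com", "Social",
    "facebook.com", "Social",
    "mslife-forum.de", "Social",
    "dmsg.de", "Organization",
    "msif.org", "Organization",
    "ccsvi-initiative.org", "Organization",
    "spiegel.de", "News",
    "msnews-daily.com", "News",
    "gesundheitskurier.de", "News",
    "kurioses.info", "Other",
    "allerlei.net", "Other",
    "esoterik-welt.de", "Other",
    "privatseite.de", "Personal",
    "meine-homepage.net", "Personal",
    "ms-tagebuch.de", "Personal",
    "wikipedia.org", "Scientific",
    "nih.gov", "Scientific",
    "fachjournal-ms.org", "Scientific",
    "amazon.com", "Commerce",
    "sanitaetshaus-online.de", "Commerce",
    "hilfsmittel-shop.com", "Commerce",
    "venenklinik.de", "HealthcareProviders",
    "gefaesspraxis.com", "HealthcareProviders",
    "ms-ambulanz.de", "HealthcareProviders"
  )
}

#' Generate a synthetic forum with planted ground truth
#'
#' Emits a corpus in which every downstream stage has a known answer: posts
#' carry planted relevance (relevant posts contain topic tokens from the
#' emitted lexicon), users post at their archetype's rates with Poisson post
#' counts and day-resolution timestamps pinned to their drawn activity span,
#' hyperlinks are drawn from the archetype's source-class preference over a
#' fixed per-class domain pool, and a thread's relevance state drifts as
#' configured. A share of users posts exactly once (participation
#' inequality). Everything is deterministic given the config seed.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_forum`: list with `corpus`
#'   ([forum_corpus()]), `truth` (list of tibbles `users`, `posts`, `links`),
#'   `lexicon` ([lexicon_model()]), `domain_map`, and `config`.
#' @export
generate_forum <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  arch <- config$archetypes
  n <- config$n_users
  day0 <- config$window[1]
  n_days <- as.integer(config$window[2] - config$window[1]) # offsets 0..n_days

  users <- sprintf("user%04d", seq_len(n))
  is_single <- runif(n) < config$single_post_share
  arch_idx <- sample.int(nrow(arch), n, replace = TRUE, prob = arch$weight)
  arch_label <- ifelse(is_single, "single_post", arch$name[arch_idx])

  # per-user schedule: first/last day offsets and per-post day offsets
  sched <- vector("list", n)
  for (i in seq_len(n)) {
    if (is_single[i]) {
      sched[[i]] <- sample.int(n_days + 1L, 1L) - 1L
      next
    }
    a <- arch_idx[i]
    rng <- arch$days_active_range[[a]]
    span <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    first <- sample.int(n_days - span + 1L, 1L) - 1L
    n_posts <- max(2L, rpois(1L, arch$posts_per_day_mean[a] * (span + 1)))
    middle <- if (n_posts > 2L) {
      first + sample.int(span + 1L, n_posts - 2L, replace = TRUE) - 1L
    } else {
      integer()
    }
    sched[[i]] <- c(first, first + span, middle)
  }

  ev_user <- rep(seq_len(n), lengths(sched))
  ev_day <- unlist(sched)
  o <- order(ev_day) # stable: within-day order is generation sequence
  ev_user <- ev_user[o]
  ev_day <- ev_day[o]
  m <- length(ev_day)
  ev_arch <- arch_idx[ev_user] # archetype row (single-posters use theirs too)

  init_p <- arch$initiation_prob[ev_arch]
  init_p[is_single[ev_user]] <- 0.5
  rel_p <- arch$relevance_prob[ev_arch]
  rel_p[is_single[ev_user]] <- 0.45
  ev_init <- runif(m) < init_p
  ev_drift <- runif(m) < config$topic_drift_prob
  ev_rel_draw <- runif(m) < rel_p
  ev_cite <- runif(m) < config$cite_prob
  ev_cite_pick <- runif(m)
  ev_join_pick <- runif(m)

  # sequential thread assignment
  thread_of <- integer(m)
  relevant <- logical(m)
  cited_idx <- integer(m) # event index of the cited post, 0 = none
  t_last <- integer(0) # last activity day per thread
  t_state <- logical(0) # current relevance state per thread
  t_posts <- list() # event indices per thread
  n_thr <- 0L
  for (i in seq_len(m)) {
    d <- ev_day[i]
    joinable <- which(t_last >= d - config$join_window)
    if (ev_init[i] || length(joinable) == 0L) {
      n_thr <- n_thr + 1L
      j <- n_thr
      t_last[j] <- d
      t_state[j] <- ev_rel_draw[i]
      t_posts[[j]] <- i
      relevant[i] <- t_state[j]
    } else {
      j <- joinable[ceiling(ev_join_pick[i] * length(joinable))]
      if (ev_drift[i]) t_state[j] <- ev_rel_draw[i]
      relevant[i] <- t_state[j]
      if (ev_cite[i]) {
        prior <- t_posts[[j]]
        cited_idx[i] <- prior[ceiling(ev_cite_pick[i] * length(prior))]
      }
      t_last[j] <- d
      t_posts[[j]] <- c(t_posts[[j]], i)
    }
    thread_of[i] <- j
  }

  post_id <- sprintf("p%06d", seq_len(m))
  thread_id <- sprintf("t%05d", thread_of)

  # hyperlinks: Poisson counts, classes from the archetype preference
  pool <- synth_domain_pool()
  pool_by_class <- split(pool$domain, pool$class)
  n_refs <- rpois(m, arch$refs_per_post_mean[ev_arch] *
                    ifelse(is_single[ev_user], 0.5, 1))
  link_post <- rep(seq_len(m), n_refs)
  n_links <- length(link_post)
  link_class <- character(n_links)
  for (a in seq_len(nrow(arch))) {
    sel <- ev_arch[link_post] == a
    if (!any(sel)) next
    link_class[sel] <- sample(domain_classes(), sum(sel), replace = TRUE,
                              prob = arch$preference_distribution[[a]])
  }
  link_domain <- vapply(link_class, function(cl) {
    ds <- pool_by_class[[cl]]
    ds[sample.int(length(ds), 1L)]
  }, character(1), USE.NAMES = FALSE)
  link_url <- paste0(
    "http://www.", link_domain, "/",
    sprintf("page%05d", sample.int(99999L, n_links, replace = TRUE))
  )

  # bodies: token streams; relevant posts carry 1-3 planted topic tokens
  topic <- synth_topic_terms()
  bg <- synth_background_vocab()
  len_target <- pmax(40, round(rnorm(m, arch$body_length_mean[ev_arch],
                                     0.25 * arch$body_length_mean[ev_arch])))
  n_topic <- ifelse(relevant & runif(m) >= config$ambiguity_prob,
                    1L + rbinom(m, 2L, 0.5), 0L)
  n_words <- pmax(1L, round(len_target / 8))
  total_words <- sum(n_words)
  word_pool <- bg[sample.int(length(bg), total_words, replace = TRUE)]
  word_of <- rep(seq_len(m), n_words)
  bodies <- vapply(split(word_pool, word_of), paste, character(1), collapse = " ")
  has_topic <- which(n_topic > 0L)
  if (length(has_topic) > 0) {
    topic_str <- vapply(has_topic, function(i) {
      paste(topic[sample.int(length(topic), n_topic[i], replace = TRUE)],
            collapse = " ")
    }, character(1))
    bodies[has_topic] <- paste(topic_str, bodies[has_topic])
  }
  urls_by_post <- rep(list(character()), m)
  if (n_links > 0) {
    split_urls <- split(link_url, link_post)
    urls_by_post[as.integer(names(split_urls))] <- split_urls
    with_links <- as.integer(names(split_urls))
    bodies[with_links] <- paste(
      bodies[with_links],
      vapply(split_urls, paste, character(1), collapse = " ")
    )
  }

  posts <- tibble::tibble(
    post_id = post_id,
    thread_id = thread_id,
    author = users[ev_user],
    timestamp = day0 + ev_day,
    body = bodies,
    cited_post_ids = lapply(cited_idx, function(ci) {
      if (ci == 0L) character() else post_id[ci]
    }),
    urls = urls_by_post
  )
  corpus <- forum_corpus(posts, window = config$window)

  truth <- list(
    users = tibble::tibble(
      user = users, archetype = arch_label, single_post = is_single
    ),
    posts = tibble::tibble(post_id = post_id, relevant = relevant),
    links = tibble::tibble(
      post_id = post_id[link_post], url = link_url,
      domain = link_domain, class = link_class
    )
  )
  lexicon <- lexicon_model(setNames(rep(1, length(topic)), topic),
                           threshold = 0.5)
  structure(
    list(
      corpus = corpus, truth = truth, lexicon = lexicon,
      domain_map = pool, config = config
    ),
    class = "synth_forum"
  )
}

#' @export
print.synth_forum <- function(x, ...) {
  cat("<synth_forum> seed", x$config$seed, "\n")
  print(x$corpus)
  print(dplyr::count(x$truth$users, .data$archetype))
  invisible(x)
}

#' Check a generated corpus against its archetype specification
#'
#' Recomputes, per archetype (multi-post users only), the empirical means of
#' the directly planted quantities — posting rate, activity span, body
#' length, references per post — and compares them with the spec within a
#' tolerance of `max(15%` of the expected value, `3` standard errors`)`.
#' Also checks the realized single-post share, the per-class concentration
#' of each archetype's links, and relevance-token consistency (every planted
#' relevant post scores above the lexicon threshold and no irrelevant post
#' does, unless ambiguity was configured).
#'
#' @param forum A `synth_forum` from [generate_forum()].
#' @return Tibble: `check`, `group`, `expected`, `observed`, `tolerance`,
#'   `ok`.
#' @export
validate_statistics <- function(forum) {
  stopifnot(inherits(forum, "synth_forum"))
  config <- forum$config
  arch <- config$archetypes
  labels <- classify_corpus(forum$corpus, forum$lexicon)
  feats <- behavior_features(forum$corpus, labels)
  feats$archetype <- forum$truth$users$archetype[
    match(feats$user, forum$truth$users$user)
  ]
  multi <- feats[feats$archetype != "single_post", , drop = FALSE]

  rows <- list()
  add <- function(check, group, expected, observed, tolerance) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, group = group, expected = expected,
      observed = observed, tolerance = tolerance,
      ok = abs(observed - expected) <= tolerance
    )
  }

  for (a in seq_len(nrow(arch))) {
    g <- multi[multi$archetype == arch$name[a], , drop = FALSE]
    if (nrow(g) < 5) next
    tol <- function(exp, sdv) max(0.15 * exp, 3 * sdv / sqrt(nrow(g)))
    add("posts_per_day", arch$name[a], arch$posts_per_day_mean[a],
        mean(g$posts_per_day), tol(arch$posts_per_day_mean[a], sd(g$posts_per_day)))
    rng <- arch$days_active_range[[a]]
    add("days_active", arch$name[a], mean(rng),
        mean(g$days_active), tol(mean(rng), sd(g$days_active)))
    add("avg_message_length", arch$name[a], arch$body_length_mean[a],
        mean(g$avg_message_length), tol(arch$body_length_mean[a], sd(g$avg_message_length)))
    add("refs_per_post", arch$name[a], arch$refs_per_post_mean[a],
        mean(g$refs_per_post), tol(arch$refs_per_post_mean[a], sd(g$refs_per_post)))
  }

  add("single_post_share", "all", config$single_post_share,
      mean(forum$truth$users$single_post),
      max(0.03, 3 * sqrt(config$single_post_share * (1 - config$single_post_share) /
                           config$n_users)))

  # link-class concentration per archetype
  links <- forum$truth$links
  links$archetype <- forum$truth$users$archetype[
    match(forum$corpus$posts$author[
      match(links$post_id, forum$corpus$posts$post_id)
    ], forum$truth$users$user)
  ]
  for (a in seq_len(nrow(arch))) {
    la <- links[links$archetype == arch$name[a], , drop = FALSE]
    if (nrow(la) < 100) next
    pref <- arch$preference_distribution[[a]]
    top <- names(pref)[which.max(pref)]
    p <- max(pref)
    add("top_class_share", arch$name[a], p, mean(la$class == top),
        max(0.1, 3 * sqrt(p * (1 - p) / nrow(la))))
  }

  # relevance-token consistency
  gold <- forum$truth$posts
  names(gold) <- c("post_id", "relevant")
  ev <- evaluate_classifier(labels, gold)
  slack <- if (config$ambiguity_prob > 0) config$ambiguity_prob + 0.05 else 1e-12
  add("relevance_precision", "all", 1, ev$precision, slack)
  add("relevance_recall", "all", 1, ev$recall, slack)

  dplyr::bind_rows(rows)
}

#' Write a generated forum to disk
#'
#' Emits `corpus.jsonl`, `truth_users.csv`, `truth_posts.csv`,
#' `truth_links.csv`, `lexicon.tsv`, and `domain_map.tsv` under `dir`.
#'
#' @param forum A `synth_forum`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(forum, dir) {
  stopifnot(inherits(forum, "synth_forum"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(forum$corpus, file.path(dir, "corpus.jsonl"))
  readr::write_csv(forum$truth$users, file.path(dir, "truth_users.csv"))
  readr::write_csv(forum$truth$posts, file.path(dir, "truth_posts.csv"))
  readr::write_csv(forum$truth$links, file.path(dir, "truth_links.csv"))
  write_lexicon(forum$lexicon, file.path(dir, "lexicon.tsv"))
  readr::write_tsv(forum$domain_map, file.path(dir, "domain_map.tsv"))
  invisible(dir)
}
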