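Package: forumminer
Title: Mining Information Sources and Behavioral Roles in Online Health Forums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining disease-community forum corpora: per-post topic
    relevance classification with a trainable weighted lexicon, hyperlink
    extraction and registrable-domain reduction against a pinned public-suffix
    table, an eight-class information-source taxonomy, scientific-publication
    reference detection against an offline catalog, the nine per-user
    contribution-behavior features and eight-dimensional source-preference
    vectors used for role discovery, a from-scratch Lloyd k-means with
    farthest-point initialization and membership-stability termination, radar
    and timeline reporting, and a synthetic forum generator that plants
    relevance labels and user archetypes so the full pipeline can be validated
    end to end without any crawl.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
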