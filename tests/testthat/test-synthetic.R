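test_that("ontology generation: id padding, textual ids, determinism", {
  cfg <- fixture_config(n_classes = 10, id_width = 7, namespace = "TOY", seed = 1)
  ont <- generate_ontology(cfg)
  expect_length(ont$classes, 10)
  expect_setequal(names(ont$classes), sprintf("TOY:%07d", 1:10))
  # a pct_textual_ids fraction get textual local ids
  cfg2 <- fixture_config(n_classes = 10, pct_textual_ids = 0.1, seed = 1)
  ids2 <- names(generate_ontology(cfg2)$classes)
  expect_identical(sum(!grepl(":[0-9]+$", ids2)), 1L)
  # same seed -> byte-identical OBO file
  p1 <- tempfile(); p2 <- tempfile()
  write_obo(generate_ontology(cfg), p1)
  write_obo(generate_ontology(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  # labels carry exact synonyms (plural + hyphenated variants)
  expect_gt(length(ont$classes[[1]]$exact_synonyms), 0)
})

test_that("id clustering puts same-head classes on adjacent ids", {
  cfg <- fixture_config(n_classes = 20, id_clustering = TRUE, seed = 5)
  meta <- attr(generate_ontology(cfg), "meta")
  # within each head group the numeric ids form one consecutive block
  num <- as.integer(sub(".*:", "", meta$class_id))
  for (h in unique(meta$head)) {
    block <- sort(num[meta$head == h])
    expect_identical(block, seq(min(block), max(block)))
  }
})

test_that("corpus generation respects the discontinuity dial", {
  cfg0 <- fixture_config(n_classes = 10, n_docs = 5, mentions_per_doc = 6,
                         pct_discontinuous = 0, seed = 2)
  docs0 <- generate_corpus(generate_ontology(cfg0), cfg0, "train")
  disc0 <- unlist(lapply(docs0, function(d)
    vapply(d$mentions, function(m) length(m$spans) > 1, logical(1))))
  expect_false(any(disc0))
  # with >= 200 mentions the empirical fraction is within +-20% relative
  cfg1 <- fixture_config(n_classes = 12, n_docs = 25, mentions_per_doc = 10,
                         pct_discontinuous = 0.3, seed = 3)
  docs1 <- generate_corpus(generate_ontology(cfg1), cfg1, "train")
  n_slots <- cfg1$n_docs * cfg1$mentions_per_doc
  n_disc <- sum(unlist(lapply(docs1, function(d)
    vapply(d$mentions, function(m) length(m$spans) > 1, logical(1)))))
  expect_gt(n_slots, 200)
  expect_gt(n_disc / n_slots, 0.3 * 0.8)
  expect_lt(n_disc / n_slots, 0.3 * 1.2)
})

test_that("Zipf skew makes token- and type-level sets differ", {
  cfg <- fixture_config(n_classes = 15, n_docs = 10, mentions_per_doc = 8,
                        zipf_exponent = 1.6, seed = 4)
  ont <- generate_ontology(cfg)
  docs <- generate_corpus(ont, cfg, "train")
  counts <- table(unlist(lapply(docs, function(d)
    vapply(d$mentions, `[[`, character(1), "class_id"))))
  # the top class accounts for a plurality of mention tokens
  expect_gt(max(counts) / sum(counts), 1.5 / length(counts))
  tok <- build_training_set(docs, ont, level = "token", augment = FALSE)
  expect_gt(max(tok$pairs$weight), 1)
})

test_that("generated corpora round trip through standoff and BIO encoding", {
  cfg <- fixture_config(n_classes = 12, n_docs = 4, mentions_per_doc = 6,
                        pct_discontinuous = 0.25, pct_overlapping = 0.2,
                        seed = 6)
  ont <- generate_ontology(cfg)
  docs <- generate_corpus(ont, cfg, "train")
  dir <- tempfile(); write_fixture(ont, docs, dir)
  expect_true(file.exists(file.path(dir, "TOY.obo")))
  has_disc <- FALSE
  for (doc in docs) {
    d2 <- read_standoff(file.path(dir, paste0(doc$doc_id, ".txt")),
                        file.path(dir, paste0(doc$doc_id, ".ann")))
    expect_identical(lapply(d2$mentions, `[`, c("spans", "class_id")),
                     lapply(doc$mentions, `[`, c("spans", "class_id")))
    # spans are token-aligned: encoding warns about nothing
    expect_silent(tg <- corpus_to_tagged(list(doc), "TOY"))
    tags <- unlist(lapply(tg, `[[`, "tags"))
    if (any(tags == "O-")) has_disc <- TRUE
  }
  expect_true(has_disc)   # pct_discontinuous > 0 shows up as O- tags
})

test_that("held-out synonyms appear only in evaluation documents", {
  cfg <- fixture_config(n_classes = 10, n_docs = 12, mentions_per_doc = 8,
                        pct_heldout_synonyms = 0.4, seed = 7)
  ont <- generate_ontology(cfg)
  meta <- attr(ont, "meta")
  held <- meta$heldout_synonym[!is.na(meta$heldout_synonym)]
  held <- held[grepl("-", held)]   # multi-word classes have true variants
  train <- generate_corpus(ont, cfg, "train")
  tr_surf <- unlist(lapply(train, function(d)
    vapply(d$mentions, `[[`, character(1), "text")))
  expect_false(any(held %in% tr_surf))
  ev <- generate_corpus(ont, cfg, "eval")
  ev_surf <- unlist(lapply(ev, function(d)
    vapply(d$mentions, `[[`, character(1), "text")))
  expect_gt(sum(ev_surf %in% held), 0)
})

test_that("generation is a pure function of the config", {
  cfg <- fixture_config(n_classes = 8, n_docs = 3, seed = 9)
  ont <- generate_ontology(cfg)
  d1 <- generate_corpus(ont, cfg, "train")
  d2 <- generate_corpus(ont, cfg, "train")
  expect_identical(d1, d2)
})
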