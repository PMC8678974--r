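test_that("character-level score gives fractional credit per position", {
  expect_equal(char_level_score("PR:000004804", "PR:000004803"), 11 / 12)
  expect_equal(round(char_level_score("PR:000004804", "PR:000004803"), 2), 0.92)
  expect_identical(char_level_score("CL:0000738", "CL:0000738"), 1)
  # truncated prediction: matches over the aligned prefix / max length
  expect_equal(char_level_score("CL:0000738", "CL:00007"), 8 / 10)
  # over-generation penalized by the same denominator rule
  expect_equal(char_level_score("CL:00007", "CL:0000738"), 8 / 10)
  expect_error(char_level_score("", "CL:1"), "empty")
})

test_that("char score is symmetric for equal lengths and 1 iff identical", {
  set.seed(1)
  for (i in 1:20) {
    a <- paste(sample(c(0:9, LETTERS[1:5]), 8, replace = TRUE), collapse = "")
    b <- paste(sample(c(0:9, LETTERS[1:5]), 8, replace = TRUE), collapse = "")
    expect_identical(char_level_score(a, b), char_level_score(b, a))
    expect_identical(char_level_score(a, b) == 1, a == b)
  }
})

test_that("normalization report: exact %, character %, non-existent %", {
  vocab <- c("PR:000004804", "PR:000004803", "SO:0001179")
  r <- evaluate_normalization(gold = c("PR:000004804", "PR:000004804"),
                              pred = c("PR:000004804", "PR:000004803"),
                              ontology_vocab = vocab)
  expect_equal(r$pct_class_id_exact, 50)
  expect_equal(r$pct_character, 100 * (1 + 11 / 12) / 2)
  expect_equal(r$pct_nonexistent_of_mismatches, 0)   # the miss is a real id
  # a fabricated id counts toward the non-existent rate
  r2 <- evaluate_normalization(c("SO:0001179", "SO:0001179"),
                               c("SO:0002000", "SO:0001179"), vocab)
  expect_equal(r2$pct_nonexistent_of_mismatches, 100)
  # perfect predictions
  r3 <- evaluate_normalization("SO:0001179", "SO:0001179", vocab)
  expect_equal(r3$pct_class_id_exact, 100)
  expect_equal(r3$pct_character, 100)
  expect_equal(r3$pct_nonexistent_of_mismatches, 0)
  expect_error(evaluate_normalization(character(), character()), "empty")
})

test_that("abstentions are misses and feed the false-negative rate", {
  r <- evaluate_normalization(
    gold = c("A:1", "A:2", "A:3", "A:4"),
    pred = c("A:1", NA, NA, NA),
    ontology_vocab = c("A:1", "A:2", "A:3", "A:4"),
    mentions = c("seen one", "unseen a", "unseen b", "unseen c"),
    training_mentions = "seen one")
  expect_equal(r$pct_class_id_exact, 25)
  expect_equal(r$pct_false_negative, 75)
  expect_equal(r$seen$pct_class_id_exact, 100)
  expect_equal(r$unseen$pct_class_id_exact, 0)
  expect_equal(r$unseen$pct_false_negative, 100)
  expect_identical(r$n_seen, 1L)
  expect_identical(r$n_unseen, 3L)
})

test_that("span evaluation: exact and Jaccard-partial matching", {
  g <- list(mention(c(0L, 16L), "A:1", doc_id = "d"),
            mention(c(20L, 25L), "A:2", doc_id = "d"))
  # identical sets are perfect either way
  for (mode in c("exact", "jaccard")) {
    r <- evaluate_spans(g, g, mode)
    expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  }
  # overlapping prediction earns fractional Jaccard credit 10/16
  p <- list(mention(c(0L, 10L), NA, doc_id = "d"))
  rj <- evaluate_spans(g[1], p, "jaccard")
  expect_equal(rj$tp, 10 / 16)
  expect_equal(rj$precision, 10 / 16)
  re <- evaluate_spans(g[1], p, "exact")
  expect_equal(re$f1, 0)
  # empty predictions: recall 0, precision reported as 0
  r0 <- evaluate_spans(g, list(), "exact")
  expect_equal(c(r0$precision, r0$recall, r0$f1), c(0, 0, 0))
  # discontinuous mentions match on the union of their characters
  dg <- list(mention(list(c(0L, 3L), c(14L, 25L)), "A:1", doc_id = "d"))
  dp <- list(mention(list(c(0L, 3L), c(14L, 25L)), NA, doc_id = "d"))
  expect_equal(evaluate_spans(dg, dp, "jaccard")$f1, 1)
  expect_equal(evaluate_spans(dg, dp, "exact")$f1, 1)
  # same spans in different documents do not match
  other <- list(mention(c(0L, 16L), NA, doc_id = "e"))
  expect_equal(evaluate_spans(g[1], other, "exact")$f1, 0)
  expect_equal(evaluate_spans(g[1], other, "jaccard")$f1, 0)
})

test_that("Jaccard-mode F1 never falls below exact-mode F1", {
  set.seed(8)
  for (i in 1:15) {
    g <- lapply(1:6, function(k) {
      a <- sample(0:80, 1); mention(c(a, a + sample(3:10, 1)),
                                    "A:1", doc_id = "d")
    })
    p <- lapply(1:6, function(k) {
      a <- sample(0:80, 1); mention(c(a, a + sample(3:10, 1)),
                                    NA, doc_id = "d")
    })
    ex <- evaluate_spans(g, p, "exact")$f1
    ja <- evaluate_spans(g, p, "jaccard")$f1
    expect_gte(ja, ex - 1e-12)
  }
})

test_that("tag F1: averaging modes and the O-exclusion switch", {
  g <- c("B", "I", "O", "O", "O", "B", "I", "O", "O", "O")
  p <- c("B", "I", "O", "O", "O", "O", "I", "O", "O", "O")
  expect_identical(tag_f1(g, g, "macro"), 1)
  expect_identical(tag_f1(g, g, "micro"), 1)
  # hand confusion arithmetic: B F1 = 2/3, I F1 = 1
  expect_equal(tag_f1(g, p, "macro", include_o = FALSE), (2 / 3 + 1) / 2)
  expect_equal(tag_f1(g, p, "micro", include_o = FALSE), 6 / 7)
  # all-O predictions on a corpus with mentions: zero without O, high micro with O
  allo <- rep("O", 10)
  expect_identical(tag_f1(g, allo, "macro", include_o = FALSE), 0)
  expect_gt(tag_f1(g, allo, "micro", include_o = TRUE), 0.5)
  expect_error(tag_f1(g, p[1:3]), "length mismatch")
})
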