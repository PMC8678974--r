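test_that("character encoding counts match the printed examples", {
  v <- char_vocab(c("white blood cell", "red blood cell", "a"),
                  c("CL:0000738", "GO:0005634"))
  e <- encode_mention("white blood cell", v, 30)
  expect_identical(attr(e, "content_length"), 16L)   # spaces included
  expect_identical(sum(e == "<sp>"), 2L)
  expect_length(e, 30)
  expect_identical(sum(e == "<pad>"), 14L)
  e2 <- encode_mention("red blood cell", v, 20)
  expect_identical(attr(e2, "content_length"), 14L)
  expect_identical(sum(e2 == "<sp>"), 2L)
  e3 <- encode_mention("a", v, 10)
  expect_identical(attr(e3, "content_length"), 1L)
  expect_identical(sum(e3 == "<pad>"), 9L)
  expect_error(encode_mention("", v, 10), "empty")
  expect_error(encode_mention("white blood cell", v, 10), "max_len")
})

test_that("class ids encode namespace, colon and local id as characters", {
  v <- char_vocab(character(), c("CL:0000738", "GO:0005634"))
  expect_identical(attr(encode_id("CL:0000738", v, 12), "content_length"), 10L)
  expect_identical(attr(encode_id("GO:0005634", v, 10), "content_length"), 10L)
  e <- encode_id("CL:0000738", v, 20)
  expect_identical(sum(e == "<pad>"), 10L)
})

test_that("detokenize inverts encoding on the symbol level", {
  texts <- c("white blood cell", "CL:0000738", "a b-c", "NCBITaxon:species")
  v <- char_vocab(texts)
  for (tx in texts)
    expect_identical(detokenize(encode_mention(tx, v, 40)), tx)
  # unknown characters surface as ?
  expect_identical(detokenize(encode_mention("a#b", v, 10)), "a?b")
})

test_that("vocabulary is bijective, deterministic and carries the specials", {
  v <- char_vocab(c("abc", "cba"), "A:12")
  expect_identical(unname(v$index[v$symbols]), seq_along(v$symbols))
  expect_true(all(c("<pad>", "<s>", "</s>", "<unk>", "<sp>") %in% v$symbols))
  expect_identical(v$symbols, char_vocab(c("cba", "abc"), "A:12")$symbols)
})

test_that("training-set assembly: levels, weights, and ontology augmentation", {
  ont <- read_obo(write_sperm_obo())
  # corpus mentioning only CL:0000232, one mention 5 times, one once
  mk_doc <- function(i, text, cid) {
    s <- segment_and_tag(text)
    document(paste0("d", i), text, s,
             list(mention(c(0L, nchar(sub(" .*", "", text))), cid)))
  }
  docs <- c(lapply(1:5, function(i) mk_doc(i, "erythrocyte seen", "CL:0000232")),
            list(mk_doc(6, "rbc observed", "CL:0000232")))
  tok <- build_training_set(docs, ont, level = "token", augment = FALSE)
  typ <- build_training_set(docs, ont, level = "type", augment = FALSE)
  expect_identical(tok$pairs$weight[tok$pairs$source == "erythrocyte"], 5)
  expect_true(all(typ$pairs$weight == 1))
  # same distinct pairs at both levels
  expect_identical(typ$pairs[c("source", "target")],
                   tok$pairs[c("source", "target")])
  # augmentation adds label + exact synonyms of the corpus-absent class
  aug <- build_training_set(docs, ont, level = "type", augment = TRUE)
  sperm <- aug$pairs[aug$pairs$target == "CL:0000019", ]
  expect_setequal(sperm$source,
                  c("sperm", "sperm cell", "spermatozoon", "spermatozoid"))
  expect_setequal(unique(sperm$origin), c("ontology-label", "ontology-synonym"))
  # the corpus-used class is not augmented
  expect_false("red blood cell" %in%
                 aug$pairs$source[aug$pairs$target == "CL:0000232"])
  # exclusion list blocks augmentation
  excl <- build_training_set(docs, ont, level = "type", augment = TRUE,
                             exclusion_list = "CL:0000019")
  expect_false("CL:0000019" %in% excl$pairs$target)
  # empty corpus without augmentation errors
  expect_error(build_training_set(list(), ont, augment = FALSE), "empty")
})

test_that("dictionary baseline: majority weight, tie-breaks, abstention", {
  ts <- structure(list(pairs = data.frame(
    source = c("cell", "cell", "membrane", "Nucleus"),
    target = c("T:2", "T:1", "T:3", "T:4"),
    weight = c(1, 3, 1, 1), origin = "corpus-annotation",
    stringsAsFactors = FALSE), level = "token", val_fraction = 0.1),
    class = "ortg_training_set")
  d <- dictionary_baseline(ts)
  expect_identical(dict_predict(d, "cell"), "T:1")         # weight 3 beats 1
  expect_identical(dict_predict(d, "nucleus"), "T:4")      # case-folded
  expect_true(is.na(dict_predict(d, "unseen thing")))
  # tie -> lexicographically smallest id
  ts$pairs$weight <- c(2, 2, 1, 1)
  expect_identical(dict_predict(dictionary_baseline(ts), "cell"), "T:1")
  # case-sensitive switch
  d2 <- dictionary_baseline(ts, case_fold = FALSE)
  expect_true(is.na(dict_predict(d2, "nucleus")))
})

test_that("pairs TSV round trips token-level occurrence counts", {
  ts <- structure(list(pairs = data.frame(
    source = c("cell", "membrane"), target = c("T:1", "T:2"),
    weight = c(3, 1), origin = "corpus-annotation", stringsAsFactors = FALSE),
    level = "token", val_fraction = 0.1), class = "ortg_training_set")
  p <- tempfile()
  write_pairs_tsv(ts, p)
  expect_length(readLines(p), 4)
  back <- read_pairs_tsv(p, "token")
  back$pairs <- back$pairs[order(back$pairs$source), ]
  rownames(back$pairs) <- NULL
  expect_identical(back$pairs$weight, c(3, 1))
  expect_identical(back$pairs$source, c("cell", "membrane"))
})

test_that("training rejects over-length configs and empty sets", {
  ts <- toy_training_set(5)
  expect_error(norm_train(ts, normalizer_config(max_source_len = 3)),
               "shorter than")
  expect_error(norm_train(ts, normalizer_config(max_target_len = 3)),
               "shorter than")
})
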