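test_that("the discontinuous + overlapping conjunction encodes as B O- B I I", {
  tags <- bio_encode(table3_sentence(), table3_mentions())
  expect_identical(tags, c("B", "O-", "B", "I", "I"))
  # precedence makes encoding order-invariant
  tags_rev <- bio_encode(table3_sentence(), rev(table3_mentions()))
  expect_identical(tags_rev, tags)
})

test_that("encoding basics: no mentions, isolated discontinuity, errors", {
  s <- table3_sentence()
  expect_identical(bio_encode(s, list()), rep("O", 5))
  # tokens a b c d with one mention (a) + (c d)
  s4 <- sentence(data.frame(text = letters[1:4], start = c(0L, 2L, 4L, 6L),
                            end = c(1L, 3L, 5L, 7L), pos = "NN",
                            stringsAsFactors = FALSE))
  m <- mention(list(c(0L, 1L), c(4L, 7L)), "TOY:1")
  expect_identical(bio_encode(s4, list(m)), c("B", "O-", "I", "I"))
  expect_error(bio_encode(s4, list(mention(c(40L, 40L + 2L), "TOY:1"))),
               "no token")
  expect_warning(bio_encode(s4, list(mention(c(0L, 2L), "TOY:1"))), "snapped")
})

test_that("decoding recovers the truncated and the discontinuous readings", {
  s <- table3_sentence()
  got <- bio_decode(s, c("B", "O-", "B", "I", "I"))
  expect_length(got, 2)
  expect_identical(got[[1]]$spans, list(text_span(0, 3)))       # "red" truncated
  expect_identical(got[[2]]$spans, list(text_span(8, 25)))      # "white blood cells"
  s4 <- sentence(data.frame(text = letters[1:4], start = c(0L, 2L, 4L, 6L),
                            end = c(1L, 3L, 5L, 7L), pos = "NN",
                            stringsAsFactors = FALSE))
  got2 <- bio_decode(s4, c("B", "O-", "I", "I"))
  expect_length(got2, 1)
  expect_identical(got2[[1]]$spans, list(text_span(0, 1), text_span(4, 7)))
  expect_identical(bio_decode(s, rep("O", 5)), list())
  # repairs: leading I starts a mention; sentence-final O- emits the held one
  expect_length(bio_decode(s4, c("O", "I", "I", "O")), 1)
  expect_length(bio_decode(s4, c("B", "I", "O-", "O-")), 1)
  expect_error(bio_decode(s4, c("B", "X", "O", "O")), "unknown tag")
  expect_error(bio_decode(s4, c("B", "O")), "length")
})

test_that("encode-decode round trips on continuous and discontinuous mentions", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    words <- replicate(n, paste(sample(letters, 3), collapse = ""))
    offs <- cumsum(c(0L, head(nchar(words) + 1L, -1L)))
    s <- sentence(data.frame(text = words, start = offs,
                             end = offs + nchar(words), pos = "NN",
                             stringsAsFactors = FALSE))
    # non-overlapping mentions: random partition into runs, some with a gap
    mentions <- list(); i <- 1
    while (i <= n - 1) {
      if (runif(1) < 0.5) {
        len <- sample(1:2, 1)
        j <- min(n, i + len - 1)
        if (runif(1) < 0.3 && j + 2 <= n) {
          mentions[[length(mentions) + 1]] <- mention(
            list(c(offs[i], offs[j] + nchar(words[j])),
                 c(offs[j + 2], offs[j + 2] + nchar(words[j + 2]))), "T:1")
          i <- j + 4   # leave an O gap so mentions stay isolated
        } else {
          mentions[[length(mentions) + 1]] <- mention(
            c(offs[i], offs[j] + nchar(words[j])), "T:1")
          i <- j + 2
        }
      } else i <- i + 1
    }
    tags <- bio_encode(s, mentions)
    expect_false(tags[1] == "O-")
    expect_false(any(tags == "I" & c("O", tags[-n])[seq_len(n)] == "O"))
    got <- bio_decode(s, tags)
    expect_identical(lapply(got, `[[`, "spans"),
                     lapply(mentions, `[[`, "spans"))
  }
})

test_that("corpus_to_tagged filters by namespace and spans sentences", {
  d <- table3_document()
  tagged <- corpus_to_tagged(list(d), "CL")
  expect_length(tagged, 1)
  expect_identical(tagged[[1]]$tags, c("B", "O-", "B", "I", "I"))
  none <- corpus_to_tagged(list(d), "GO")
  expect_identical(none[[1]]$tags, rep("O", 5))
  # two sentences, mentions in each
  txt <- "red cells divide . white cells migrate ."
  toks <- strsplit(txt, " ")[[1]]
  offs <- cumsum(c(0L, head(nchar(toks) + 1L, -1L)))
  sents <- list(
    sentence(data.frame(text = toks[1:4], start = offs[1:4],
                        end = offs[1:4] + nchar(toks[1:4]), pos = "NN",
                        stringsAsFactors = FALSE)),
    sentence(data.frame(text = toks[5:8], start = offs[5:8],
                        end = offs[5:8] + nchar(toks[5:8]), pos = "NN",
                        stringsAsFactors = FALSE)))
  d2 <- document("d2", txt, sents,
                 list(mention(c(offs[1], offs[2] + 5L), "CL:1"),
                      mention(c(offs[5], offs[6] + 5L), "CL:2")))
  tg <- corpus_to_tagged(list(d2), "CL")
  expect_length(tg, 2)
  expect_identical(tg[[1]]$tags[1:2], c("B", "I"))
  expect_identical(tg[[2]]$tags[1:2], c("B", "I"))
  # cross-sentence mention dropped with a warning
  d3 <- document("d3", txt, sents,
                 list(mention(c(offs[2], offs[5] + 5L), "CL:3")))
  expect_warning(expect_warning(tg3 <- corpus_to_tagged(list(d3), "CL"),
                                "crosses"), "crosses")
  expect_true(all(unlist(lapply(tg3, `[[`, "tags")) == "O"))
})

test_that("CoNLL two-column export/import round trips tokens and tags", {
  tagged <- corpus_to_tagged(list(table3_document()), "CL")
  p <- tempfile()
  write_conll(tagged, p)
  expect_true(any(grepl("\tO-$", readLines(p))))   # file literal is O-
  back <- read_conll(p)
  expect_identical(back[[1]]$tags, tagged[[1]]$tags)
  expect_identical(back[[1]]$sentence$text, tagged[[1]]$sentence$text)
})
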