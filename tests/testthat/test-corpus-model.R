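test_that("span and mention invariants are enforced", {
  expect_error(text_span(3, 3), "invalid span")
  expect_error(text_span(-1, 2), "invalid span")
  expect_silent(text_span(0, 1))
  expect_error(mention(list(c(0, 5), c(3, 8))), "non-overlapping")
  expect_error(mention(list(c(10, 12), c(0, 2))), "sorted")
  m <- mention(list(c(0, 3), c(14, 25)), "CL:0000232")
  expect_length(m$spans, 2)
  expect_true(ontorecog:::is_discontinuous(m))
})

test_that("document validates mention bounds and reconstructs covered text", {
  expect_error(document("d", "short", mentions = list(mention(c(0, 99)))),
               "exceeds document bounds")
  d <- table3_document()
  expect_identical(d$mentions[[1]]$text, "red ... blood cells")
  expect_identical(d$mentions[[2]]$text, "white blood cells")
  expect_error(
    document("d", "red and white blood cells",
             mentions = list(mention(c(0, 3), "CL:1", text = "wrong"))),
    "mismatch")
})

test_that("read_obo keeps exact synonyms of non-obsolete terms", {
  ont <- read_obo(write_sperm_obo())
  expect_length(ont$classes, 2)           # obsolete excluded
  sperm <- ont$classes[["CL:0000019"]]
  expect_identical(sperm$label, "sperm")
  expect_setequal(sperm$exact_synonyms,
                  c("sperm cell", "spermatozoon", "spermatozoid"))
  # RELATED synonym filtered under the default scope
  expect_length(ont$classes[["CL:0000232"]]$exact_synonyms, 0)
  # widened scope switch
  ont2 <- read_obo(write_sperm_obo(), synonym_scopes = c("EXACT", "RELATED"))
  expect_identical(ont2$classes[["CL:0000232"]]$exact_synonyms, "RBC")
})

test_that("read_obo handles empty input and rejects malformed stanzas", {
  p <- tempfile(); writeLines(character(), p)
  expect_length(read_obo(p)$classes, 0)
  writeLines(c("[Term]", "id: A:1", "name: x", "[Term]", "id: A:1", "name: y"), p)
  expect_error(read_obo(p), "duplicate")
  writeLines(c("[Term]", "name before id???"), p)
  expect_error(read_obo(p), "malformed")
})

test_that("OBO round trip is the identity and order-stable", {
  ont <- read_obo(write_sperm_obo(), keep_obsolete = TRUE)
  p1 <- tempfile(); p2 <- tempfile()
  write_obo(ont, p1)
  ont2 <- read_obo(p1, keep_obsolete = TRUE)
  expect_identical(names(ont$classes), names(ont2$classes))
  expect_identical(ont$classes, ont2$classes)
  write_obo(ont2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("read_standoff parses discontinuous mentions and validates text", {
  txt <- tempfile(fileext = ".txt"); ann <- tempfile(fileext = ".ann")
  writeChar("red and white blood cells", txt, eos = NULL)
  writeLines(c("T1\tCL:0000232 0 3;14 25\tred ... blood cells",
               "T2\tCL:0000738 8 25\twhite blood cells"), ann)
  d <- read_standoff(txt, ann)
  expect_length(d$mentions, 2)
  expect_identical(d$mentions[[1]]$spans,
                   list(text_span(0, 3), text_span(14, 25)))
  expect_identical(d$mentions[[2]]$text, "white blood cells")
  # covered-text mismatch names the annotation
  writeLines("T1\tCL:0000232 0 3\tnope", ann)
  expect_error(read_standoff(txt, ann), "T1")
  # offsets out of range
  writeLines("T7\tCL:0000232 0 400\tx", ann)
  expect_error(read_standoff(txt, ann), "T7")
  # empty annotation file
  writeLines(character(), ann)
  expect_length(read_standoff(txt, ann)$mentions, 0)
})

test_that("overlapping annotations are preserved as distinct mentions", {
  txt <- tempfile(); ann <- tempfile()
  writeChar("red and white blood cells", txt, eos = NULL)
  writeLines(c("T1\tCL:0000232 14 25\tblood cells",
               "T2\tCL:0000738 8 25\twhite blood cells"), ann)
  d <- read_standoff(txt, ann)
  expect_length(d$mentions, 2)
})

test_that("standoff write/read round trip reproduces mentions exactly", {
  d <- table3_document()
  ann <- tempfile(); txt <- tempfile()
  write_standoff(d, ann, txt)
  d2 <- read_standoff(txt, ann, doc_id = "t3")
  expect_identical(lapply(d$mentions, `[`, c("spans", "class_id", "text")),
                   lapply(d2$mentions, `[`, c("spans", "class_id", "text")))
  # zero mentions -> zero T-lines
  d0 <- document("e", "no annotations here")
  write_standoff(d0, ann)
  expect_length(readLines(ann), 0)
})

test_that("standoff round trip is byte-idempotent on random synthetic mentions", {
  d <- random_mention_doc(100, seed = 7)
  a1 <- tempfile(); a2 <- tempfile(); txt <- tempfile()
  write_standoff(d, a1, txt)
  d2 <- read_standoff(txt, a1)
  write_standoff(d2, a2)
  expect_identical(readLines(a1), readLines(a2))
})

test_that("segment_and_tag yields offset-faithful tokens and sentence splits", {
  s <- segment_and_tag("Cells divide.")
  expect_length(s, 1)
  expect_identical(s[[1]]$start, c(0L, 6L, 12L))
  expect_identical(s[[1]]$end, c(5L, 12L, 13L))
  expect_identical(segment_and_tag(""), list())
  two <- segment_and_tag("Cells divide. Nuclei migrate.")
  expect_length(two, 2)
  # token spans reconstruct the source text
  text <- "Cells divide. Nuclei migrate."
  for (sent in two)
    for (i in seq_len(nrow(sent)))
      expect_identical(substr(text, sent$start[i] + 1, sent$end[i]),
                       sent$text[i])
})
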