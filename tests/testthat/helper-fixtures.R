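# Shared fixtures, built in code.

# "red and white blood cells": the canonical discontinuous + overlapping
# example. CL:0000232 (red blood cell) = "red" + "blood cells",
# CL:0000738 (white blood cell) = "white blood cells".
table3_sentence <- function() {
  sentence(data.frame(
    text = c("red", "and", "white", "blood", "cells"),
    start = c(0L, 4L, 8L, 14L, 20L),
    end = c(3L, 7L, 13L, 19L, 25L),
    pos = c("JJ", "CC", "JJ", "NN", "NNS"),
    stringsAsFactors = FALSE))
}

table3_mentions <- function() {
  list(mention(list(c(0L, 3L), c(14L, 25L)), "CL:0000232"),
       mention(list(c(8L, 25L)), "CL:0000738"))
}

table3_document <- function() {
  document("t3", "red and white blood cells",
           sentences = list(table3_sentence()),
           mentions = table3_mentions())
}

# A minimal OBO source with the sperm-cell class, a RELATED-synonym class,
# and an obsolete class.
sperm_obo_lines <- function() {
  c("format-version: 1.2",
    "",
    "[Term]",
    "id: CL:0000019",
    "name: sperm",
    'synonym: "sperm cell" EXACT []',
    'synonym: "spermatozoon" EXACT []',
    'synonym: "spermatozoid" EXACT []',
    "",
    "[Term]",
    "id: CL:0000232",
    "name: red blood cell",
    'synonym: "RBC" RELATED []',
    "",
    "[Term]",
    "id: CL:0009999",
    "name: defunct cell",
    "is_obsolete: true")
}

write_sperm_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(sperm_obo_lines(), path)
  path
}

# small toy training set for normalizer unit tests
toy_training_set <- function(n = 12) {
  srcs <- paste0("mention", letters[seq_len(n)])
  tgts <- paste0("TOY:", formatC(seq_len(n), width = 5, flag = "0"))
  structure(list(pairs = data.frame(source = srcs, target = tgts,
                                    weight = 1, origin = "corpus-annotation",
                                    stringsAsFactors = FALSE),
                 level = "type", val_fraction = 0.1),
            class = "ortg_training_set")
}

random_mention_doc <- function(n_mentions = 100, seed = 1) {
  set.seed(seed)
  words <- replicate(60, paste(sample(letters, 5, replace = TRUE), collapse = ""))
  text <- paste(words, collapse = " ")
  offs <- cumsum(c(0L, head(nchar(words), -1L) + 1L))
  mentions <- lapply(seq_len(n_mentions), function(i) {
    k <- sample(58, 1)
    if (runif(1) < 0.3) {
      spans <- list(c(offs[k], offs[k] + nchar(words[k])),
                    c(offs[k + 2], offs[k + 2] + nchar(words[k + 2])))
    } else {
      spans <- list(c(offs[k], offs[k + 1] + nchar(words[k + 1])))
    }
    mention(spans, sprintf("TOY:%07d", sample(999, 1)))
  })
  document(paste0("rand", seed), text, mentions = mentions)
}
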