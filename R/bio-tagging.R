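# BIO(-) tag scheme for discontinuous and overlapping concept mentions.
#
# Tags: B = first token of a mention's first span, I = any other mention
# token, O- = token lying strictly between two spans of a discontinuous
# mention, O = everything else. Per-token conflicts between overlapping
# mentions resolve by precedence B > I > O- > O, so beginnings of mentions
# are always preserved even when the rest of a multi-word mention is not.

BIO_TAGS <- c("B", "I", "O-", "O")
TAG_PRECEDENCE <- c(B = 4L, I = 3L, `O-` = 2L, O = 1L)

#' Encode gold mentions over a sentence as a BIO(-) tag sequence
#'
#' For each mention, the first token of its first span gets `B`, remaining
#' tokens of all spans get `I`, and tokens strictly between consecutive
#' spans of a discontinuous mention get `O-`. When overlapping mentions
#' propose different tags for a token, the higher-precedence tag wins
#' (B > I > O- > O), which makes the encoding deterministic regardless of
#' the order mentions are supplied in.
#'
#' Mention spans that do not fall exactly on token boundaries are snapped
#' outward to the covering tokens with a warning; mentions lying outside the
#' sentence raise an error.
#'
#' @param sent a [sentence()].
#' @param mentions list of [mention()] objects whose spans lie within the
#'   sentence's token range.
#' @return Character vector of tags, one per token.
#' @export
bio_encode <- function(sent, mentions) {
  n <- nrow(sent)
  prec <- rep(TAG_PRECEDENCE[["O"]], n)
  tags <- rep("O", n)
  propose <- function(idx, tag) {
    p <- TAG_PRECEDENCE[[tag]]
    upd <- prec[idx] < p
    tags[idx[upd]] <<- tag
    prec[idx[upd]] <<- p
  }
  for (m in mentions) {
    span_tokens <- lapply(m$spans, function(s) {
      idx <- which(sent$start < s[2L] & sent$end > s[1L])
      if (!length(idx))
        stop("mention span [", s[1L], ",", s[2L],
             ") references no token of the sentence")
      if (sent$start[idx[1L]] != s[1L] || sent$end[idx[length(idx)]] != s[2L])
        warning("mention span [", s[1L], ",", s[2L],
                ") snapped outward to token boundaries")
      idx
    })
    first <- span_tokens[[1L]][1L]
    all_tok <- unlist(span_tokens)
    propose(setdiff(all_tok, first), "I")
    propose(first, "B")
    if (length(span_tokens) > 1L) {
      for (k in seq_len(length(span_tokens) - 1L)) {
        gap_lo <- max(span_tokens[[k]]) + 1L
        gap_hi <- min(span_tokens[[k + 1L]]) - 1L
        if (gap_lo <= gap_hi) propose(gap_lo:gap_hi, "O-")
      }
    }
  }
  tags
}

#' Decode a BIO(-) tag sequence back to mention spans
#'
#' A maximal `B I*` run forms a mention span. An `O-` run after a mention
#' holds the mention open: if the run is followed by `I`, that `I`-run is
#' appended as a further span of the same (discontinuous) mention; if
#' followed by `B` or `O` (or sentence end), the held mention is emitted as
#' is — the truncation behavior the tag scheme implies for overlapping
#' conjunctions. A leading or post-`O` `I` starts a new mention at that
#' token (ill-formed sequences are repaired, never rejected).
#'
#' @param sent a [sentence()].
#' @param tags character vector over `{B, I, O, O-}`, one per token.
#' @return List of [mention()] objects with `class_id = NA`; character spans
#'   are derived from the token offsets.
#' @export
bio_decode <- function(sent, tags) {
  if (length(tags) != nrow(sent))
    stop("tag sequence length ", length(tags), " != token count ", nrow(sent))
  bad <- setdiff(unique(tags), BIO_TAGS)
  if (length(bad)) stop("unknown tag(s): ", paste(bad, collapse = ", "))
  mentions <- list()
  cur_spans <- NULL    # list of c(first_token, last_token) runs
  cur_run <- NULL      # c(first, last) of the open token run
  in_gap <- FALSE      # inside an O- run with a held mention
  close_run <- function() {
    if (!is.null(cur_run)) cur_spans[[length(cur_spans) + 1L]] <<- cur_run
    cur_run <<- NULL
  }
  emit <- function() {
    close_run()
    if (length(cur_spans)) {
      spans <- lapply(cur_spans, function(r)
        text_span(sent$start[r[1L]], sent$end[r[2L]]))
      mentions[[length(mentions) + 1L]] <<- mention(spans)
    }
    cur_spans <<- NULL
    in_gap <<- FALSE
  }
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag == "B") {
      emit()
      cur_run <- c(i, i)
    } else if (tag == "I") {
      if (!is.null(cur_run) && cur_run[2L] == i - 1L) {
        cur_run[2L] <- i
      } else if (in_gap && length(cur_spans)) {
        cur_run <- c(i, i)           # new span of the held discontinuous mention
        in_gap <- FALSE
      } else {
        emit()                        # leading I: repair as mention start
        cur_run <- c(i, i)
      }
    } else if (tag == "O-") {
      close_run()
      if (length(cur_spans)) in_gap <- TRUE else in_gap <- FALSE
    } else {                          # O
      emit()
    }
  }
  emit()
  mentions
}

#' Convert annotated documents to a tagged training corpus
#'
#' Encodes every sentence of every document, keeping only mentions whose
#' class-id namespace matches `namespace` (models are trained per ontology).
#' Mentions crossing sentence boundaries are dropped with a warning; the
#' sequence models are sentence-scoped.
#'
#' @param documents list of [document()] objects with tokenized sentences.
#' @param namespace ontology namespace filter (e.g. `"CL"`).
#' @return List with one element per sentence:
#'   `list(sentence =, tags =, doc_id =)`.
#' @export
corpus_to_tagged <- function(documents, namespace) {
  out <- list()
  for (doc in documents) {
    for (sent in doc$sentences) {
      lo <- sent$start[1L]; hi <- sent$end[nrow(sent)]
      keep <- list()
      for (m in doc$mentions) {
        if (!identical(mention_namespace(m), namespace)) next
        starts <- vapply(m$spans, `[[`, integer(1), 1L)
        ends <- vapply(m$spans, `[[`, integer(1), 2L)
        inside <- starts >= lo & ends <= hi
        if (all(inside)) {
          keep[[length(keep) + 1L]] <- m
        } else if (any(starts < hi & ends > lo)) {
          warning("mention ", m$class_id, " in ", doc$doc_id,
                  " crosses a sentence boundary; dropped")
        }
      }
      out[[length(out) + 1L]] <- list(sentence = sent,
                                      tags = bio_encode(sent, keep),
                                      doc_id = doc$doc_id)
    }
  }
  out
}

#' Write / read a tagged corpus in two-column CoNLL style
#'
#' One `token<TAB>tag` line per token, blank line between sentences. The
#' file tag literal for the inter-span tag is `O-`. Offsets and POS are not
#' stored, so a round trip preserves tokens and tags only.
#'
#' @param tagged list as returned by [corpus_to_tagged()].
#' @param path output path.
#' @return `path` invisibly (`write`), or a tagged list whose sentences carry
#'   synthesized offsets and rule-tagger POS (`read`).
#' @export
write_conll <- function(tagged, path) {
  lines <- unlist(lapply(tagged, function(p)
    c(paste(p$sentence$text, p$tags, sep = "\t"), "")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  groups <- split(lines, cumsum(lines == ""))
  out <- list()
  for (g in groups) {
    g <- g[nzchar(g)]
    if (!length(g)) next
    parts <- do.call(rbind, strsplit(g, "\t", fixed = TRUE))
    words <- parts[, 1L]
    offs <- cumsum(c(0L, head(nchar(words), -1L) + 1L))
    sent <- sentence(data.frame(text = words, start = offs,
                                end = offs + nchar(words),
                                pos = rule_pos_tagger(words),
                                stringsAsFactors = FALSE))
    out[[length(out) + 1L]] <- list(sentence = sent, tags = parts[, 2L],
                                    doc_id = NA_character_)
  }
  out
}
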