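#' @importFrom stats optim runif setNames rbinom
#' @importFrom utils head tail
NULL

# ---- domain constructors ----------------------------------------------------

#' Create a text span
#'
#' Character offsets are 0-based and half-open: `start` is the offset of the
#' first character, `end` the offset one past the last (the brat/BioNLP
#' standoff convention).
#'
#' @param start integer offset, 0-based inclusive.
#' @param end integer offset, 0-based exclusive; must exceed `start`.
#' @return An integer vector `c(start, end)` of class `ortg_span`.
#' @export
text_span <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single integers")
  if (start < 0L || start >= end)
    stop("invalid span: need 0 <= start < end, got [", start, ", ", end, ")")
  structure(c(start = start, end = end), class = "ortg_span")
}

#' Create a concept mention
#'
#' A mention covers one or more ordered, non-overlapping spans; two or more
#' spans make the mention discontinuous. Covered text of a discontinuous
#' mention joins the span texts with `" ... "`.
#'
#' @param spans list of spans (each `text_span()` or a length-2 integer
#'   vector), sorted by start, pairwise non-overlapping.
#' @param class_id ontology class identifier string (may be `NA` for
#'   detected-but-unnormalized mentions).
#' @param text covered text, if known.
#' @param doc_id optional document identifier.
#' @return Object of class `ortg_mention`.
#' @export
mention <- function(spans, class_id = NA_character_, text = NULL, doc_id = NULL) {
  if (!is.list(spans)) spans <- list(spans)
  spans <- lapply(spans, function(s) {
    if (!inherits(s, "ortg_span")) s <- text_span(s[[1]], s[[2]])
    s
  })
  starts <- vapply(spans, `[[`, integer(1), 1L)
  ends   <- vapply(spans, `[[`, integer(1), 2L)
  if (is.unsorted(starts, strictly = TRUE) && length(spans) > 1L)
    stop("mention spans must be sorted by start")
  if (length(spans) > 1L && any(starts[-1L] < ends[-length(ends)]))
    stop("mention spans must be pairwise non-overlapping")
  structure(list(spans = spans, class_id = class_id, text = text,
                 doc_id = doc_id),
            class = "ortg_mention")
}

#' @export
format.ortg_mention <- function(x, ...) {
  sp <- paste(vapply(x$spans, function(s) paste0("[", s[1L], ",", s[2L], ")"),
                     character(1)), collapse = ";")
  paste0("<mention ", x$class_id, " ", sp,
         if (!is.null(x$text)) paste0(" \"", x$text, "\""), ">")
}

#' @export
print.ortg_mention <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

mention_text_from <- function(doc_text, spans) {
  paste(vapply(spans, function(s) substr(doc_text, s[1L] + 1L, s[2L]),
               character(1)), collapse = " ... ")
}

is_discontinuous <- function(m) length(m$spans) > 1L

mention_namespace <- function(m) sub(":.*$", "", m$class_id)

#' Create a sentence from a token table
#'
#' @param tokens data frame with columns `text`, `start`, `end`, `pos`
#'   (0-based half-open character offsets, strictly increasing and
#'   non-overlapping).
#' @return The token data frame with class `ortg_sentence`.
#' @export
sentence <- function(tokens) {
  stopifnot(is.data.frame(tokens),
            all(c("text", "start", "end", "pos") %in% names(tokens)))
  if (nrow(tokens) > 1L) {
    if (is.unsorted(tokens$start, strictly = TRUE))
      stop("token spans must be strictly increasing")
    if (any(tokens$start[-1L] < tokens$end[-nrow(tokens)]))
      stop("token spans must not overlap")
  }
  if (any(tokens$end <= tokens$start)) stop("empty token span")
  class(tokens) <- c("ortg_sentence", "data.frame")
  tokens
}

#' Create a document
#'
#' @param doc_id document identifier.
#' @param text full document text.
#' @param sentences list of [sentence()] token tables.
#' @param mentions list of [mention()] objects; each span must lie within the
#'   document bounds and its covered text is validated against `text`.
#' @return Object of class `ortg_document`.
#' @export
document <- function(doc_id, text, sentences = list(), mentions = list()) {
  n <- nchar(text)
  for (m in mentions) {
    for (s in m$spans)
      if (s[2L] > n) stop("mention span exceeds document bounds in ", doc_id)
    recon <- mention_text_from(text, m$spans)
    if (!is.null(m$text) && !identical(m$text, recon))
      stop("mention text mismatch in ", doc_id, ": stored \"", m$text,
           "\" vs document \"", recon, "\"")
  }
  mentions <- lapply(mentions, function(m) {
    m$text <- mention_text_from(text, m$spans)
    m$doc_id <- doc_id
    m
  })
  structure(list(doc_id = doc_id, text = text, sentences = sentences,
                 mentions = mentions),
            class = "ortg_document")
}

#' Create an ontology class record
#'
#' Class identifiers are `namespace:local_id`; the local part is usually
#' numeric (zero-padded digits) but may be textual (e.g. a taxonomic-rank
#' name or an extension-class label).
#'
#' @param class_id full identifier string, containing exactly one `:`
#'   separating namespace from local id.
#' @param label primary name.
#' @param exact_synonyms character vector of exact synonyms.
#' @param obsolete logical flag.
#' @return Object of class `ortg_class`.
#' @export
ontology_class <- function(class_id, label, exact_synonyms = character(),
                           obsolete = FALSE) {
  if (!nzchar(class_id) || !grepl(":", class_id, fixed = TRUE))
    stop("class_id must be namespace:local, got \"", class_id, "\"")
  structure(list(class_id = class_id, label = label,
                 exact_synonyms = as.character(exact_synonyms),
                 obsolete = isTRUE(obsolete)),
            class = "ortg_class")
}

#' Create an ontology
#'
#' @param namespace ontology namespace (no colon).
#' @param classes list of [ontology_class()] records with unique ids.
#' @return Object of class `ortg_ontology`; classes are kept in input order
#'   and indexed by class id.
#' @export
ontology <- function(namespace, classes = list()) {
  if (grepl(":", namespace, fixed = TRUE)) stop("namespace must not contain ':'")
  ids <- vapply(classes, `[[`, character(1), "class_id")
  if (anyDuplicated(ids))
    stop("duplicate class id: ", ids[duplicated(ids)][1L])
  names(classes) <- ids
  structure(list(namespace = namespace, classes = classes),
            class = "ortg_ontology")
}

#' @export
print.ortg_ontology <- function(x, ...) {
  cat("<ontology ", x$namespace, ": ", length(x$classes), " classes>\n", sep = "")
  invisible(x)
}

ontology_ids <- function(ont) names(ont$classes)

# ---- OBO flat-file reader / writer ------------------------------------------

#' Read an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 flat file, keeping `id`, `name`
#' and synonyms. By default only synonyms with scope `EXACT` are retained;
#' `synonym_scopes` may widen this. Obsolete terms are recorded but excluded
#' from the returned ontology unless `keep_obsolete = TRUE`.
#'
#' @param path OBO file path.
#' @param synonym_scopes character vector of synonym scopes to keep.
#' @param keep_obsolete keep `is_obsolete: true` terms?
#' @return An [ontology()] whose namespace is taken from the first class id
#'   (empty ontology gets namespace `""`).
#' @export
read_obo <- function(path, synonym_scopes = "EXACT", keep_obsolete = FALSE) {
  lines <- readLines(path, warn = FALSE)
  classes <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$id)) stop("OBO [Term] stanza without id (near line ", cur$line, ")")
    if (is.null(cur$name)) cur$name <- ""
    if (!is.null(classes[[cur$id]]))
      stop("duplicate OBO id: ", cur$id)
    classes[[cur$id]] <<- ontology_class(cur$id, cur$name, cur$syn, cur$obsolete)
    invisible()
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (startsWith(line, "[")) {
      flush(cur); cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(line = i, syn = character(), obsolete = FALSE)
      next
    }
    if (!in_term) next
    if (!grepl("^[A-Za-z_]+:", line))
      stop("malformed OBO line ", i, ": \"", lines[i], "\"")
    key <- sub(":.*$", "", line)
    val <- trimws(sub("^[A-Za-z_]+: ?", "", line))
    val <- sub(" *!.*$", "", val)   # strip trailing comments
    if (key == "id") {
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    } else if (key == "synonym") {
      m <- regmatches(val, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z_]*)', val))[[1]]
      if (length(m) < 2L)
        stop("malformed OBO synonym at line ", i, ": \"", lines[i], "\"")
      syn_text <- gsub('\\\\(.)', "\\1", m[2])
      scope <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "RELATED"
      if (scope %in% synonym_scopes) cur$syn <- c(cur$syn, syn_text)
    }
    # other keys (def, is_a, xref, ...) are ignored
  }
  flush(cur)
  if (!keep_obsolete)
    classes <- Filter(function(cl) !cl$obsolete, classes)
  ns <- if (length(classes)) mention_namespace(classes[[1]]) else ""
  ontology(ns, unname(classes))
}

#' Write an ontology as an OBO flat file
#'
#' Emits one `[Term]` stanza per class with `id`, `name`, and EXACT-scoped
#' `synonym` lines; output is deterministic (input order, fixed header) so a
#' seeded generator yields byte-identical files.
#'
#' @param ont an [ontology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  out <- c("format-version: 1.2", "")
  for (cl in ont$classes) {
    out <- c(out, "[Term]",
             paste0("id: ", cl$class_id),
             paste0("name: ", cl$label),
             vapply(cl$exact_synonyms,
                    function(s) paste0('synonym: "', gsub('"', '\\\\"', s),
                                       '" EXACT []'),
                    character(1), USE.NAMES = FALSE),
             if (cl$obsolete) "is_obsolete: true" else character(),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

# ---- standoff annotation reader / writer ------------------------------------

#' Read a text + standoff annotation pair
#'
#' Annotation lines follow the brat/BioNLP convention
#' `T<k>\t<CLASS_ID> <start> <end>[;<start> <end>]*\t<covered text>`, with the
#' annotation type being the raw ontology class id. Semicolon-separated
#' offset pairs form one discontinuous mention; covered text (spans joined by
#' `" ... "`) is validated against the document.
#'
#' @param text_path path to the `.txt` document.
#' @param ann_path path to the `.ann` standoff file.
#' @param sentences optional pre-tokenized sentences to attach (see
#'   [segment_and_tag()]).
#' @param doc_id document id; defaults to the text file stem.
#' @return An [document()].
#' @export
read_standoff <- function(text_path, ann_path, sentences = NULL, doc_id = NULL) {
  text <- readChar(text_path, file.size(text_path), useBytes = FALSE)
  if (is.null(doc_id)) doc_id <- sub("\\.txt$", "", basename(text_path))
  lines <- readLines(ann_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  mentions <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !grepl("^T\\d+$", parts[1]))
      stop("malformed standoff line: \"", line, "\"")
    tid <- parts[1]
    head_bits <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    class_id <- head_bits[1]
    offs <- strsplit(paste(head_bits[-1], collapse = " "), ";", fixed = TRUE)[[1]]
    spans <- lapply(offs, function(o) {
      se <- suppressWarnings(as.integer(strsplit(trimws(o), " ")[[1]]))
      if (length(se) != 2L || anyNA(se))
        stop("malformed offsets in annotation ", tid)
      if (se[2] > nchar(text))
        stop("offsets out of range in annotation ", tid)
      text_span(se[1], se[2])
    })
    m <- mention(spans, class_id)
    covered <- mention_text_from(text, spans)
    if (length(parts) >= 3L && !identical(parts[3], covered))
      stop("covered text mismatch in annotation ", tid, ": file has \"",
           parts[3], "\" but document reads \"", covered, "\"")
    m
  })
  document(doc_id, text, sentences %||% list(), mentions)
}

#' Write a document's mentions as a standoff annotation file
#'
#' Inverse of [read_standoff()]: `read_standoff()` of the written file
#' reproduces the mention set exactly.
#'
#' @param doc an [document()].
#' @param ann_path output `.ann` path.
#' @param text_path optional path to also write the document text.
#' @return `ann_path`, invisibly.
#' @export
write_standoff <- function(doc, ann_path, text_path = NULL) {
  lines <- character(length(doc$mentions))
  for (i in seq_along(doc$mentions)) {
    m <- doc$mentions[[i]]
    offs <- paste(vapply(m$spans, function(s) paste(s[1L], s[2L]),
                         character(1)), collapse = ";")
    lines[i] <- paste0("T", i, "\t", m$class_id, " ", offs, "\t",
                       mention_text_from(doc$text, m$spans))
  }
  writeLines(lines, ann_path)
  if (!is.null(text_path)) writeChar(doc$text, text_path, eos = NULL)
  invisible(ann_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- tokenization and part-of-speech tagging --------------------------------

#' A small deterministic rule-based POS tagger
#'
#' Assigns Penn-style tags from word shape: digits -> CD, sentence
#' punctuation -> its own tag, capitalized -> NNP, common function words from
#' a fixed table, plural-looking -> NNS, else NN. Intended as the fallback
#' when gold tags are not supplied; the synthetic generator always supplies
#' gold tags, and any `function(words) tags` can be plugged in instead.
#'
#' @param words character vector of token strings.
#' @return Character vector of tags, same length.
#' @export
rule_pos_tagger <- function(words) {
  closed <- c(the = "DT", a = "DT", an = "DT", and = "CC", or = "CC",
              of = "IN", "in" = "IN", on = "IN", to = "TO", is = "VBZ",
              are = "VBP", was = "VBD", were = "VBD", "for" = "IN",
              with = "IN", by = "IN", we = "PRP", it = "PRP")
  vapply(words, function(w) {
    lw <- tolower(w)
    if (grepl("^[0-9]+([.,][0-9]+)*$", w)) return("CD")
    if (grepl("^[[:punct:]]$", w)) return(w)
    if (!is.na(closed[lw])) return(unname(closed[lw]))
    if (grepl("^[A-Z]", w)) return("NNP")
    if (grepl("[a-z]s$", w) && !grepl("(ss|us|is)$", w)) return("NNS")
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

#' Segment text into sentences of offset-carrying tokens
#'
#' Tokens are maximal runs of non-space, non-punctuation characters, or
#' single punctuation marks; sentences break after `.`, `!` or `?` tokens.
#' Each token carries its 0-based half-open character offsets into the
#' original text, so the text is exactly reconstructable.
#'
#' @param text document string.
#' @param tagger function mapping a character vector of token strings to a
#'   same-length vector of POS tags; default [rule_pos_tagger()].
#' @return List of [sentence()] token tables (empty list for empty text).
#' @export
segment_and_tag <- function(text, tagger = rule_pos_tagger) {
  if (!nzchar(text)) return(list())
  pat <- "[^\\s.,;:!?()\\[\\]\"']+|[.,;:!?()\\[\\]\"']"
  mm <- gregexpr(pat, text, perl = TRUE)
  m <- mm[[1]]
  if (m[1] == -1L) return(list())
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  words <- regmatches(text, mm)[[1]]
  ends <- starts + lens
  sent_end <- words %in% c(".", "!", "?")
  sent_id <- c(0L, cumsum(sent_end))[seq_along(words)]
  tags <- tagger(words)
  lapply(split(seq_along(words), sent_id), function(idx) {
    sentence(data.frame(text = words[idx], start = starts[idx],
                        end = ends[idx], pos = tags[idx],
                        stringsAsFactors = FALSE))
  })
}
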