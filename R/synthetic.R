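# Seeded generators for toy ontologies and annotated corpora that exhibit
# the statistical structure the pipeline assumes: Zipf-skewed mention
# frequencies (so token- and type-level training sets differ), synonym
# variation with some synonyms held out of training, conjunction-ellipsis
# constructions yielding discontinuous mentions overlapping a continuous
# one, nested mentions, and optional id clustering in which classes with
# related labels receive numerically adjacent identifiers. Everything is a
# pure function of the configuration, seed included.

FIXTURE_MODIFIERS <- c("red", "white", "basal", "apical", "cortical",
                       "medullary", "dorsal", "ventral", "distal", "proximal",
                       "ciliated", "granular", "squamous", "cuboidal",
                       "columnar", "spindle", "stellate", "fusiform",
                       "pigmented", "mural", "lateral", "septal", "germinal",
                       "luminal", "radial")
FIXTURE_HEADS <- c("cell", "membrane", "nucleus", "receptor", "neuron",
                   "fiber", "vesicle", "granule", "tissue", "gland", "duct",
                   "follicle", "plate", "layer", "ridge", "pore", "channel",
                   "tubule", "crest", "node")
FIXTURE_FILLER <- c("the", "study", "showed", "that", "observed", "analysis",
                    "within", "results", "samples", "were", "during",
                    "development", "expression", "we", "found", "data",
                    "experiments", "measured", "specific", "between",
                    "among", "indicated", "levels", "increased", "reduced")
FIXTURE_POS <- c(setNames(rep("JJ", length(FIXTURE_MODIFIERS)), FIXTURE_MODIFIERS),
                 setNames(rep("NN", length(FIXTURE_HEADS)), FIXTURE_HEADS),
                 setNames(rep("NNS", length(FIXTURE_HEADS)),
                          paste0(FIXTURE_HEADS, "s")),
                 nuclei = "NNS",
                 the = "DT", study = "NN", showed = "VBD", that = "IN",
                 observed = "VBD", analysis = "NN", within = "IN",
                 results = "NNS", samples = "NNS", were = "VBD",
                 during = "IN", development = "NN", expression = "NN",
                 we = "PRP", found = "VBD", data = "NNS",
                 experiments = "NNS", measured = "VBD", specific = "JJ",
                 between = "IN", among = "IN", indicated = "VBD",
                 levels = "NNS", increased = "VBD", reduced = "VBD",
                 and = "CC", "." = ".")

#' Configuration for the synthetic ontology/corpus generators
#'
#' @param n_classes number of ontology classes (>= 2).
#' @param id_width digit width of numeric local ids.
#' @param namespace ontology namespace.
#' @param pct_textual_ids fraction of classes given textual local ids.
#' @param n_docs documents to generate.
#' @param mentions_per_doc mention instances per document.
#' @param zipf_exponent skew of the class frequency distribution (class
#'   probability proportional to rank^-exponent; 0 = uniform).
#' @param pct_discontinuous fraction of mention instances realized as a
#'   conjunction-ellipsis construction ("X and Y Z"), producing one
#'   discontinuous mention overlapping a continuous one.
#' @param pct_overlapping fraction of instances additionally annotated with
#'   a nested single-head mention.
#' @param pct_heldout_synonyms fraction of classes whose hyphenated synonym
#'   is reserved for evaluation documents only.
#' @param id_clustering give classes sharing a head word numerically
#'   adjacent ids?
#' @param seed RNG seed; all outputs are pure functions of this config.
#' @return List of class `ortg_fixture_config`.
#' @export
fixture_config <- function(n_classes = 20L, id_width = 7L, namespace = "TOY",
                           pct_textual_ids = 0, n_docs = 10L,
                           mentions_per_doc = 5L, zipf_exponent = 1,
                           pct_discontinuous = 0, pct_overlapping = 0,
                           pct_heldout_synonyms = 0, id_clustering = FALSE,
                           seed = 1L) {
  stopifnot(n_classes >= 2L,
            pct_textual_ids >= 0, pct_textual_ids <= 1,
            pct_discontinuous >= 0, pct_discontinuous <= 1,
            pct_overlapping >= 0, pct_overlapping <= 1,
            pct_heldout_synonyms >= 0, pct_heldout_synonyms <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 id_width = as.integer(id_width), namespace = namespace,
                 pct_textual_ids = pct_textual_ids,
                 n_docs = as.integer(n_docs),
                 mentions_per_doc = as.integer(mentions_per_doc),
                 zipf_exponent = zipf_exponent,
                 pct_discontinuous = pct_discontinuous,
                 pct_overlapping = pct_overlapping,
                 pct_heldout_synonyms = pct_heldout_synonyms,
                 id_clustering = isTRUE(id_clustering),
                 seed = as.integer(seed)),
            class = "ortg_fixture_config")
}

pluralize <- function(head) {
  if (head == "nucleus") "nuclei" else paste0(head, "s")
}

#' Generate a toy ontology
#'
#' Builds `n_classes` classes with multi-word labels ("modifier head") drawn
#' from a fixed seeded vocabulary. Each class gets two exact synonyms: the
#' plural form and a hyphenated variant (the one reserved for evaluation when
#' synonym holdout is requested). When `pct_overlapping > 0` a few
#' single-word (head-only) classes are included so nested mentions are
#' possible. Numeric ids are zero-padded to `id_width` and assigned in
#' head-sorted order when `id_clustering` is on (so classes sharing a head
#' word get adjacent ids) or in label-shuffled order otherwise; a
#' `pct_textual_ids` fraction instead get textual local ids derived from the
#' label.
#'
#' @param cfg a [fixture_config()].
#' @return An [ontology()]; each class carries attributes in
#'   `attr(ont, "meta")` (data frame with `class_id`, `label`, `head`,
#'   `heldout_synonym`).
#' @export
generate_ontology <- function(cfg) {
  set.seed(cfg$seed)
  n_single <- if (cfg$pct_overlapping > 0) min(length(FIXTURE_HEADS),
                                               ceiling(cfg$n_classes * 0.2)) else 0L
  n_multi <- cfg$n_classes - n_single
  combos <- expand.grid(mod = FIXTURE_MODIFIERS, head = FIXTURE_HEADS,
                        stringsAsFactors = FALSE)
  if (n_multi > nrow(combos)) stop("fixture vocabulary too small")
  # sample heads first so labels cluster on a few heads (conjunctions need
  # classes sharing a head word)
  heads_used <- sample(FIXTURE_HEADS, max(2L, ceiling(n_multi / 4)))
  combos <- combos[combos$head %in% heads_used, ]
  pick <- combos[sample(nrow(combos), n_multi), ]
  labels <- paste(pick$mod, pick$head)
  heads <- pick$head
  if (n_single > 0L) {
    sh <- sample(unique(heads), min(n_single, length(unique(heads))))
    extra <- setdiff(FIXTURE_HEADS, sh)
    if (length(sh) < n_single) sh <- c(sh, extra[seq_len(n_single - length(sh))])
    labels <- c(labels, sh)
    heads <- c(heads, sh)
  }
  ord <- if (cfg$id_clustering) order(heads, labels) else sample(length(labels))
  labels <- labels[ord]; heads <- heads[ord]
  n_text <- round(cfg$pct_textual_ids * cfg$n_classes)
  textual <- rep(FALSE, cfg$n_classes)
  if (n_text > 0L) textual[sample(cfg$n_classes, n_text)] <- TRUE
  local <- character(cfg$n_classes)
  if (cfg$id_clustering) {
    # realistic identifier layout: each head group occupies a block of
    # sequentially adjacent ids, and the blocks themselves are spread across
    # the full digit space (curated ontologies look like this: related
    # classes adjacent, the id set far from dense)
    grp <- match(heads, unique(heads))
    sizes <- tabulate(grp)
    segment <- floor((10^cfg$id_width - 1) / length(sizes))
    bases <- vapply(seq_along(sizes), function(g)
      (g - 1) * segment + sample.int(max(1L, segment - sizes[g]), 1L),
      numeric(1))
    num <- bases[grp] + sequence(sizes) - 1   # grp is sorted here
    local[!textual] <- formatC(num[!textual], width = cfg$id_width,
                               flag = "0", format = "d")
  } else {
    local[!textual] <- formatC(seq_len(sum(!textual)), width = cfg$id_width,
                               flag = "0", format = "d")
  }
  local[textual] <- gsub(" ", "_", labels[textual])
  ids <- paste0(cfg$namespace, ":", local)
  heldout <- rep(FALSE, cfg$n_classes)
  n_ho <- round(cfg$pct_heldout_synonyms * cfg$n_classes)
  if (n_ho > 0L) heldout[sample(cfg$n_classes, n_ho)] <- TRUE
  classes <- lapply(seq_len(cfg$n_classes), function(i) {
    words <- strsplit(labels[i], " ", fixed = TRUE)[[1]]
    plural <- paste(c(head(words, -1L), pluralize(tail(words, 1L))),
                    collapse = " ")
    hyph <- paste(words, collapse = "-")
    syns <- unique(setdiff(c(plural, hyph), labels[i]))
    ontology_class(ids[i], labels[i], syns)
  })
  ont <- ontology(cfg$namespace, classes)
  attr(ont, "meta") <- data.frame(
    class_id = ids, label = labels, head = heads,
    heldout_synonym = ifelse(heldout,
                             vapply(labels, function(l)
                               paste(strsplit(l, " ")[[1]], collapse = "-"),
                               character(1)),
                             NA_character_),
    stringsAsFactors = FALSE)
  ont
}

# surface realizations of a class usable for a given split
class_surfaces <- function(ont, i, split) {
  meta <- attr(ont, "meta")
  cl <- ont$classes[[i]]
  surf <- c(cl$label, cl$exact_synonyms)
  ho <- meta$heldout_synonym[i]
  if (!is.na(ho)) {
    if (split == "train") surf <- setdiff(surf, ho)
    else surf <- ho   # evaluation docs mention held-out classes via the
                      # reserved synonym only
  }
  surf
}

#' Generate an annotated synthetic corpus
#'
#' Emits `n_docs` documents of filler-vocabulary sentences, each embedding
#' one mention whose class is drawn by a Zipf law over the ontology. A
#' `pct_discontinuous` fraction is realized as a conjunction ellipsis
#' ("red and white cells") annotated as one discontinuous mention (first
#' modifier + shared head) overlapping a continuous one; a `pct_overlapping`
#' fraction nests a single-head mention inside a multi-word one. Gold POS
#' tags come from a fixed per-word table, and all mention spans align to
#' token boundaries. With `split = "eval"`, classes flagged for synonym
#' holdout are mentioned only via their reserved synonym.
#'
#' @param ont ontology from [generate_ontology()].
#' @param cfg the same [fixture_config()].
#' @param split `"train"` or `"eval"`.
#' @param seed RNG seed; defaults to `cfg$seed` (+1 for eval).
#' @return List of [document()] objects.
#' @export
generate_corpus <- function(ont, cfg, split = c("train", "eval"),
                            seed = NULL) {
  split <- match.arg(split)
  if (is.null(seed)) seed <- cfg$seed + (split == "eval")
  set.seed(seed)
  meta <- attr(ont, "meta")
  n <- length(ont$classes)
  ranks <- seq_len(n)
  probs <- ranks^(-cfg$zipf_exponent)
  probs <- probs / sum(probs)
  # heads with >= 2 multi-word classes support the conjunction construction
  multi <- grepl(" ", meta$label)
  conj_heads <- names(which(table(meta$head[multi]) >= 2L))
  single_idx <- which(!multi)
  docs <- vector("list", cfg$n_docs)
  for (d in seq_len(cfg$n_docs)) {
    tok_text <- character(); tok_pos <- character(); sent_break <- integer()
    men_tok <- list()   # list(tokens = indices per span, class_id)
    add_tok <- function(words) {
      idx <- length(tok_text) + seq_along(words)
      pos <- unname(FIXTURE_POS[words])
      if (anyNA(pos)) pos[is.na(pos)] <- rule_pos_tagger(words[is.na(pos)])
      tok_text <<- c(tok_text, words)
      tok_pos <<- c(tok_pos, pos)
      idx
    }
    for (s in seq_len(cfg$mentions_per_doc)) {
      add_tok(sample(FIXTURE_FILLER, sample(2:4, 1L)))
      r <- runif(1L)
      if (r < cfg$pct_discontinuous && length(conj_heads)) {
        hd <- sample(conj_heads, 1L)
        cand <- which(multi & meta$head == hd)
        pr <- probs[cand] / sum(probs[cand])
        ab <- sample(cand, 2L, prob = pr)
        mod_a <- strsplit(meta$label[ab[1L]], " ")[[1]][1L]
        mod_b <- strsplit(meta$label[ab[2L]], " ")[[1]][1L]
        head_pl <- pluralize(hd)
        ia <- add_tok(mod_a); ic <- add_tok("and"); ib <- add_tok(mod_b)
        ih <- add_tok(head_pl)
        men_tok[[length(men_tok) + 1L]] <-
          list(spans = list(ia, ih), class_id = meta$class_id[ab[1L]])
        men_tok[[length(men_tok) + 1L]] <-
          list(spans = list(c(ib, ih)), class_id = meta$class_id[ab[2L]])
      } else {
        i <- sample(n, 1L, prob = probs)
        surf <- sample(class_surfaces(ont, i, split), 1L)
        words <- strsplit(surf, " ", fixed = TRUE)[[1]]
        idx <- add_tok(words)
        men_tok[[length(men_tok) + 1L]] <-
          list(spans = list(idx), class_id = meta$class_id[i])
        if (runif(1L) < cfg$pct_overlapping && length(single_idx) &&
            length(words) > 1L) {
          hd <- tail(strsplit(meta$label[i], " ")[[1]], 1L)
          j <- single_idx[meta$label[single_idx] == hd]
          if (length(j) == 1L)
            men_tok[[length(men_tok) + 1L]] <-
              list(spans = list(tail(idx, 1L)), class_id = meta$class_id[j])
        }
      }
      add_tok(sample(FIXTURE_FILLER, sample(1:3, 1L)))
      add_tok(".")
      sent_break <- c(sent_break, length(tok_text))
    }
    starts <- cumsum(c(0L, head(nchar(tok_text), -1L) + 1L))
    ends <- starts + nchar(tok_text)
    text <- paste(tok_text, collapse = " ")
    sent_id <- findInterval(seq_along(tok_text) - 1L, sent_break) + 1L
    sents <- lapply(base::split(seq_along(tok_text), sent_id), function(ii)
      sentence(data.frame(text = tok_text[ii], start = starts[ii],
                          end = ends[ii], pos = tok_pos[ii],
                          stringsAsFactors = FALSE)))
    mentions <- lapply(men_tok, function(mt) {
      spans <- lapply(mt$spans, function(ii)
        text_span(starts[ii[1L]], ends[ii[length(ii)]]))
      mention(spans, mt$class_id)
    })
    docs[[d]] <- document(sprintf("%s-%s-%03d", cfg$namespace, split, d),
                          text, sents, mentions)
  }
  docs
}

#' Write a fixture to disk (.obo, .txt, .ann)
#'
#' @param ont ontology.
#' @param docs document list.
#' @param dir output directory (created).
#' @return `dir` invisibly.
#' @export
write_fixture <- function(ont, docs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_obo(ont, file.path(dir, paste0(ont$namespace, ".obo")))
  for (doc in docs) {
    writeChar(doc$text, file.path(dir, paste0(doc$doc_id, ".txt")), eos = NULL)
    write_standoff(doc, file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}
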