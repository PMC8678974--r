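# Concept normalization as character-level sequence translation: mention
# text in, ontology class identifier out, one character at a time. Training
# pairs come from corpus annotations, optionally augmented with ontology
# labels and exact synonyms of classes never mentioned in the corpus, at the
# token level (occurrence counts kept as weights) or the type level (one
# mapping per distinct pair).

SPECIALS <- c(PAD = "<pad>", BOS = "<s>", EOS = "</s>", UNK = "<unk>",
              SP = "<sp>")

#' Build a character vocabulary
#'
#' Symbol inventory: every character observed in the source and target
#' strings (the inter-word space as the explicit `<sp>` symbol) plus the
#' special symbols `<pad>`, `<s>`, `</s>`, `<unk>`. The symbol-to-index
#' mapping is bijective and deterministic (radix-sorted characters).
#'
#' @param sources,targets character vectors of mention texts and class ids.
#' @return Object of class `ortg_vocab`: `symbols` (character vector) and
#'   `index` (named integer lookup).
#' @export
char_vocab <- function(sources, targets = character()) {
  chars <- unique(unlist(strsplit(c(sources, targets), "", fixed = TRUE)))
  chars <- sort(setdiff(chars, " "), method = "radix")
  symbols <- c(unname(SPECIALS), chars)
  structure(list(symbols = symbols,
                 index = setNames(seq_along(symbols), symbols)),
            class = "ortg_vocab")
}

#' @export
print.ortg_vocab <- function(x, ...) {
  cat("<character vocab: ", length(x$symbols), " symbols>\n", sep = "")
  invisible(x)
}

#' Encode a mention or class id as a character-token sequence
#'
#' One token per character, inter-word spaces as `<sp>`, characters outside
#' the vocabulary as `<unk>`, end-padded with `<pad>` to `max_len`. The
#' content length (tokens before padding) equals the character count of the
#' string including spaces, and is attached as attribute `content_length`.
#'
#' `encode_id()` is the same encoding applied to a class identifier: the
#' namespace, colon, and local-id characters are all included.
#'
#' @param text non-empty string of at most `max_len` characters.
#' @param vocab a [char_vocab()].
#' @param max_len padded sequence length.
#' @return Character vector of symbols, length `max_len`.
#' @export
encode_mention <- function(text, vocab, max_len) {
  if (!nzchar(text)) stop("cannot encode an empty string")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  if (length(chars) > max_len)
    stop("\"", text, "\" has ", length(chars), " characters > max_len ", max_len)
  syms <- ifelse(chars == " ", SPECIALS[["SP"]],
                 ifelse(chars %in% vocab$symbols, chars, SPECIALS[["UNK"]]))
  out <- c(syms, rep(SPECIALS[["PAD"]], max_len - length(syms)))
  attr(out, "content_length") <- length(syms)
  out
}

#' @rdname encode_mention
#' @param class_id class identifier string.
#' @export
encode_id <- function(class_id, vocab, max_len) encode_mention(class_id, vocab, max_len)

#' Detokenize a symbol sequence back to a string
#'
#' Inverse of [encode_mention()] on the symbol level: `<sp>` becomes a
#' space; `<pad>`, `<s>` and `</s>` are dropped; `<unk>` becomes `?`.
#'
#' @param symbols character vector of vocabulary symbols.
#' @return The decoded string.
#' @export
detokenize <- function(symbols) {
  symbols <- symbols[!symbols %in% SPECIALS[c("PAD", "BOS", "EOS")]]
  symbols[symbols == SPECIALS[["SP"]]] <- " "
  symbols[symbols == SPECIALS[["UNK"]]] <- "?"
  paste(symbols, collapse = "")
}

#' Assemble a normalization training set
#'
#' Collects (mention text, class id) pairs from the documents' annotations
#' for the ontology's namespace, at the `token` level (distinct pairs with
#' their occurrence counts as weights) or the `type` level (distinct pairs,
#' weight 1). With `augment = TRUE`, every ontology class that never occurs
#' as a corpus annotation and is not on the `exclusion_list` contributes its
#' primary label and each exact synonym as additional quasi-mention pairs.
#'
#' @param documents list of [document()] objects.
#' @param ontology an [ontology()].
#' @param level `"token"` or `"type"`.
#' @param augment add label/synonym pairs for corpus-absent classes?
#' @param exclusion_list class ids never to augment with (curated unused
#'   classes).
#' @return Object of class `ortg_training_set`: data frame `pairs` with
#'   columns `source`, `target`, `weight`, `origin`, plus `level`.
#' @export
build_training_set <- function(documents, ontology, level = c("token", "type"),
                               augment = TRUE, exclusion_list = character()) {
  level <- match.arg(level)
  src <- tgt <- character()
  for (doc in documents) {
    for (m in doc$mentions) {
      if (!identical(mention_namespace(m), ontology$namespace)) next
      src <- c(src, m$text)
      tgt <- c(tgt, m$class_id)
    }
  }
  if (length(src)) {
    key <- paste(src, tgt, sep = "\r")
    tab <- table(key)
    uniq <- strsplit(names(tab), "\r", fixed = TRUE)
    pairs <- data.frame(source = vapply(uniq, `[[`, character(1), 1L),
                        target = vapply(uniq, `[[`, character(1), 2L),
                        weight = if (level == "token") as.numeric(tab) else 1,
                        origin = "corpus-annotation",
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(source = character(), target = character(),
                        weight = numeric(), origin = character(),
                        stringsAsFactors = FALSE)
  }
  if (augment) {
    used <- unique(tgt)
    for (cl in ontology$classes) {
      if (cl$class_id %in% used || cl$class_id %in% exclusion_list) next
      texts <- c(cl$label, cl$exact_synonyms)
      texts <- texts[nzchar(texts)]
      if (!length(texts)) next
      pairs <- rbind(pairs, data.frame(
        source = texts, target = cl$class_id, weight = 1,
        origin = c("ontology-label",
                   rep("ontology-synonym", length(texts) - 1L)),
        stringsAsFactors = FALSE))
    }
  }
  if (!nrow(pairs)) stop("training set is empty")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, level = level, val_fraction = 0.1),
            class = "ortg_training_set")
}

#' @export
print.ortg_training_set <- function(x, ...) {
  cat("<training set: ", nrow(x$pairs), " distinct pairs (", x$level,
      " level, total weight ", sum(x$pairs$weight), ")>\n", sep = "")
  invisible(x)
}

#' Normalizer configuration
#'
#' Desk-scale defaults for the character-level translator: a single-layer
#' bidirectional encoder and single-layer decoder with global multiplicative
#' attention, Adam, greedy decoding.
#'
#' @param embedding_dim character embedding width.
#' @param hidden_dim recurrent state width (per direction).
#' @param n_layers encoder/decoder depth; this implementation supports 1.
#' @param max_source_len,max_target_len padded lengths; `NULL` = longest
#'   training sequence.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param val_fraction held-out validation share of the pairs (the 90-10
#'   split).
#' @param seed RNG seed controlling initialization, the split, and batch
#'   order; identical seeds give identical validation-loss trajectories.
#' @return List of class `ortg_norm_config`.
#' @export
normalizer_config <- function(embedding_dim = 32L, hidden_dim = 64L,
                              n_layers = 1L, max_source_len = NULL,
                              max_target_len = NULL, epochs = 400L,
                              batch_size = 32L, learning_rate = 0.005,
                              val_fraction = 0.1, seed = 1L) {
  if (n_layers != 1L)
    stop("this implementation supports n_layers = 1")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim), n_layers = 1L,
                 attention = "multiplicative",
                 max_source_len = max_source_len,
                 max_target_len = max_target_len,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "ortg_norm_config")
}

# Pack pairs into index matrices for the network.
norm_tensors <- function(pairs, vocab, max_src, max_tgt) {
  idx_of <- function(text, max_len) {
    syms <- encode_mention(text, vocab, max_len)
    unname(vocab$index[syms])
  }
  SRC <- t(vapply(pairs$source, idx_of, integer(max_src), max_len = max_src))
  TGT <- t(vapply(pairs$target, idx_of, integer(max_tgt), max_len = max_tgt))
  pad <- vocab$index[[SPECIALS[["PAD"]]]]
  bos <- vocab$index[[SPECIALS[["BOS"]]]]
  eos <- vocab$index[[SPECIALS[["EOS"]]]]
  # target-in: <s> + chars; target-out: chars + </s> (then pads)
  Tt <- max_tgt + 1L
  n <- nrow(TGT)
  TGT_in <- cbind(rep(bos, n), TGT)
  TGT_out <- cbind(TGT, rep(pad, n))
  for (i in seq_len(n)) {
    cl <- sum(TGT[i, ] != pad)
    TGT_out[i, cl + 1L] <- eos
  }
  tmask <- matrix(as.numeric(TGT_out != pad), n, Tt)
  smask <- matrix(as.numeric(SRC != pad), n, max_src)
  dimnames(SRC) <- dimnames(TGT_in) <- dimnames(TGT_out) <- NULL
  list(SRC = SRC, smask = smask, TGT_in = TGT_in, TGT_out = TGT_out,
       tmask = tmask)
}

#' Train the character-level translation normalizer
#'
#' Teacher-forced training of the attention encoder-decoder on the 90%
#' split, tracking validation loss on the held-out 10% each epoch. Pair
#' weights (token-level occurrence counts) multiply the loss. Fully
#' reproducible per seed.
#'
#' @param ts an [build_training_set()] result.
#' @param config a [normalizer_config()].
#' @param quiet suppress the per-epoch progress line?
#' @return Object of class `ortg_normalizer` carrying the parameters,
#'   vocabulary, sequence lengths, and the loss history.
#' @export
norm_train <- function(ts, config = normalizer_config(), quiet = TRUE) {
  pairs <- ts$pairs
  if (!nrow(pairs)) stop("training set is empty")
  vocab <- char_vocab(pairs$source, pairs$target)
  max_src <- max(nchar(pairs$source))
  max_tgt <- max(nchar(pairs$target))
  if (!is.null(config$max_source_len)) {
    if (config$max_source_len < max_src)
      stop("max_source_len shorter than the longest training mention")
    max_src <- config$max_source_len
  }
  if (!is.null(config$max_target_len)) {
    if (config$max_target_len < max_tgt)
      stop("max_target_len shorter than the longest training id")
    max_tgt <- config$max_target_len
  }
  set.seed(config$seed)
  n <- nrow(pairs)
  n_val <- if (n >= 10L) max(1L, round(config$val_fraction * n)) else 0L
  val_idx <- if (n_val > 0L) sample(n, n_val) else integer()
  tr_idx <- setdiff(seq_len(n), val_idx)
  tens <- norm_tensors(pairs, vocab, max_src, max_tgt)
  w <- pairs$weight
  p <- s2s_init_params(length(vocab$symbols), config$embedding_dim,
                       config$hidden_dim, config$seed)
  state <- list(m = s2s_zero_like(p), v = s2s_zero_like(p))
  step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  slice <- function(idx) lapply(tens, function(x) x[idx, , drop = FALSE])
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      sl <- slice(b)
      lg <- s2s_loss_grad(p, sl$SRC, sl$smask, sl$TGT_in, sl$TGT_out,
                          sl$tmask, w[b])
      g <- s2s_clip(lg$grad)
      step <- step + 1L
      upd <- s2s_adam_update(p, g, state, config$learning_rate, step)
      p <- upd$p; state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(b)
    }
    val_loss <- if (length(val_idx)) {
      sl <- slice(val_idx)
      s2s_loss_grad(p, sl$SRC, sl$smask, sl$TGT_in, sl$TGT_out, sl$tmask,
                    w[val_idx])$loss
    } else NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / length(tr_idx),
                                         val_loss = val_loss))
    if (!quiet && epoch %% 25L == 0L)
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                      ep_loss / length(tr_idx), val_loss))
  }
  structure(list(params = p, vocab = vocab, max_source_len = max_src,
                 max_target_len = max_tgt, config = config,
                 history = history,
                 training_mentions = unique(pairs$source)),
            class = "ortg_normalizer")
}

#' @export
print.ortg_normalizer <- function(x, ...) {
  cat("<normalizer: vocab ", length(x$vocab$symbols), ", src len ",
      x$max_source_len, ", tgt len ", x$max_target_len, ", ",
      nrow(x$history), " epochs>\n", sep = "")
  invisible(x)
}

#' Predict class identifiers for mention strings
#'
#' Greedy decoding until the end symbol or the maximum target length; the
#' translator never abstains — every input yields a non-empty identifier
#' string (if the very first decoding step emits the end symbol, the best
#' non-special symbol is taken instead).
#'
#' @param model an `ortg_normalizer`.
#' @param mentions character vector of mention texts. Mentions longer than
#'   the model's source length are truncated to it.
#' @return Character vector of predicted identifier strings.
#' @export
norm_predict <- function(model, mentions) {
  if (!length(mentions)) return(character())
  vocab <- model$vocab
  ml <- model$max_source_len
  mentions_t <- vapply(mentions, function(m) {
    if (!nzchar(m)) " " else if (nchar(m) > ml) substr(m, 1L, ml) else m
  }, character(1), USE.NAMES = FALSE)
  idx_of <- function(text) unname(vocab$index[encode_mention(text, vocab, ml)])
  SRC <- t(vapply(mentions_t, idx_of, integer(ml)))
  dimnames(SRC) <- NULL
  pad <- vocab$index[[SPECIALS[["PAD"]]]]
  smask <- matrix(as.numeric(SRC != pad), nrow(SRC), ml)
  out <- s2s_greedy(model$params, SRC, smask,
                    bos = vocab$index[[SPECIALS[["BOS"]]]],
                    eos = vocab$index[[SPECIALS[["EOS"]]]],
                    max_len = model$max_target_len + 1L)
  special_idx <- vocab$index[unname(SPECIALS)]
  vapply(seq_len(nrow(out)), function(i) {
    ids <- out[i, ]
    ids <- ids[ids != 0L]
    s <- detokenize(vocab$symbols[ids])
    if (!nzchar(s)) {
      # degenerate: force the best non-special first symbol
      k <- setdiff(seq_along(vocab$symbols), special_idx)[1L]
      s <- vocab$symbols[k]
    }
    s
  }, character(1))
}

#' Dictionary-lookup normalization baseline
#'
#' Exact-string lookup over the training pairs (case-folded by default).
#' Conflicting targets for one source resolve to the highest total weight,
#' ties to the lexicographically smallest id. Unseen mentions get `NA`
#' (no prediction), which downstream evaluation counts as a false negative —
#' the defining weakness of dictionary methods relative to the translator,
#' which always answers.
#'
#' @param ts an [build_training_set()] result.
#' @param case_fold fold case before matching?
#' @return Object of class `ortg_dictionary`; use [dict_predict()].
#' @export
dictionary_baseline <- function(ts, case_fold = TRUE) {
  pairs <- ts$pairs
  if (!nrow(pairs)) stop("training set is empty")
  key <- if (case_fold) tolower(pairs$source) else pairs$source
  agg <- stats::aggregate(weight ~ key + target,
                          data = data.frame(key = key, target = pairs$target,
                                            weight = pairs$weight),
                          FUN = sum)
  agg <- agg[order(agg$key, -agg$weight, agg$target), ]
  lut <- agg$target[!duplicated(agg$key)]
  names(lut) <- agg$key[!duplicated(agg$key)]
  structure(list(lookup = lut, case_fold = case_fold),
            class = "ortg_dictionary")
}

#' @rdname dictionary_baseline
#' @param dict an `ortg_dictionary`.
#' @param mentions character vector of mention texts.
#' @return `dict_predict()`: character vector with `NA` for unseen mentions.
#' @export
dict_predict <- function(dict, mentions) {
  key <- if (dict$case_fold) tolower(mentions) else mentions
  unname(dict$lookup[key])
}

#' Write / read training pairs as two-column TSV
#'
#' `mention<TAB>class_id`, one line per pair occurrence (token-level weights
#' are expanded to repeated lines so the file is self-describing).
#'
#' @param ts training set.
#' @param path file path.
#' @param level level to assign on read.
#' @return `path` invisibly, or a training set.
#' @export
write_pairs_tsv <- function(ts, path) {
  reps <- rep(seq_len(nrow(ts$pairs)), times = ts$pairs$weight)
  writeLines(paste(ts$pairs$source[reps], ts$pairs$target[reps], sep = "\t"),
             path)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path, level = c("token", "type")) {
  level <- match.arg(level)
  lines <- readLines(path, warn = FALSE)
  parts <- do.call(rbind, strsplit(lines[nzchar(lines)], "\t", fixed = TRUE))
  key <- paste(parts[, 1L], parts[, 2L], sep = "\r")
  tab <- table(key)
  uniq <- strsplit(names(tab), "\r", fixed = TRUE)
  pairs <- data.frame(source = vapply(uniq, `[[`, character(1), 1L),
                      target = vapply(uniq, `[[`, character(1), 2L),
                      weight = if (level == "token") as.numeric(tab) else 1,
                      origin = "corpus-annotation", stringsAsFactors = FALSE)
  structure(list(pairs = pairs, level = level, val_fraction = 0.1),
            class = "ortg_training_set")
}
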