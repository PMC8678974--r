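# Linear-chain conditional random field over BIO(-) tags.
#
# Implemented from first principles: sparse indicator features, exact
# forward-backward gradients, L-BFGS optimization with an elastic-net
# penalty (the L1 term smoothed as sqrt(x^2 + eps) so a quasi-Newton
# optimizer applies). Feature template per token: lowercased word identity,
# case shape, the three preceding word identities, the token's own POS tag,
# and the POS tags of the next two tokens, with boundary sentinels.

#' Token feature template for the CRF
#'
#' @param sent a [sentence()].
#' @param index token position, 1-based.
#' @return Named character vector of feature strings
#'   (`w=`, `shape=`, `w-1=` .. `w-3=`, `pos=`, `pos+1=`, `pos+2=`).
#' @export
extract_features <- function(sent, index) {
  n <- nrow(sent)
  if (index < 1L || index > n) stop("token index out of range")
  word_at <- function(i) if (i >= 1L) tolower(sent$text[i]) else "<s>"
  pos_at  <- function(i) if (i <= n) sent$pos[i] else "</s>"
  w <- sent$text[index]
  c(w      = paste0("w=", tolower(w)),
    shape  = paste0("shape=", word_shape(w)),
    `w-1`  = paste0("w-1=", word_at(index - 1L)),
    `w-2`  = paste0("w-2=", word_at(index - 2L)),
    `w-3`  = paste0("w-3=", word_at(index - 3L)),
    pos    = paste0("pos=", sent$pos[index]),
    `pos+1` = paste0("pos+1=", pos_at(index + 1L)),
    `pos+2` = paste0("pos+2=", pos_at(index + 2L)))
}

word_shape <- function(w) {
  if (!grepl("[A-Za-z]", w)) return("non-alpha")
  if (grepl("^[a-z]+$", w)) return("all-lower")
  if (grepl("^[A-Z]+$", w)) return("all-upper")
  if (grepl("^[A-Z][a-z]+$", w)) return("init-cap")
  "mixed"
}

#' CRF configuration
#'
#' @param l1,l2 non-negative regularization penalties (used by [crf_train()]
#'   directly; starting values are ignored by [crf_tune()]).
#' @param n_candidates number of (l1, l2) pairs drawn in randomized search.
#' @param cv_folds_tuning folds for the tuning cross-validation.
#' @param cv_folds_eval folds for final evaluation.
#' @param objective tag-F1 averaging optimized during tuning: `"macro"`
#'   (default, computed over B/I/O- only, since O dominance inflates micro)
#'   or `"micro"`.
#' @param include_o include the O tag in the tuning objective?
#' @param max_iter L-BFGS iteration cap.
#' @param seed RNG seed for candidate sampling and fold assignment.
#' @return List of class `ortg_crf_config`.
#' @export
crf_config <- function(l1 = 0.1, l2 = 0.1, n_candidates = 50L,
                       cv_folds_tuning = 3L, cv_folds_eval = 5L,
                       objective = c("macro", "micro"), include_o = FALSE,
                       max_iter = 200L, seed = 1L) {
  stopifnot(l1 >= 0, l2 >= 0, is.finite(l1), is.finite(l2))
  structure(list(l1 = l1, l2 = l2, n_candidates = as.integer(n_candidates),
                 cv_folds_tuning = as.integer(cv_folds_tuning),
                 cv_folds_eval = as.integer(cv_folds_eval),
                 objective = match.arg(objective), include_o = include_o,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "ortg_crf_config")
}

# Build the sparse design for a tagged corpus: one row per token, indicator
# columns indexed by feature string. Returns the model-ready structure.
crf_design <- function(tagged, feat_index = NULL) {
  feats <- lapply(tagged, function(p)
    lapply(seq_len(nrow(p$sentence)), function(i) extract_features(p$sentence, i)))
  all_feats <- unlist(feats, use.names = FALSE)
  if (is.null(feat_index)) {
    feat_index <- setNames(seq_along(unique(all_feats)), unique(all_feats))
  }
  tok_feats <- unlist(lapply(feats, function(s) s), recursive = FALSE)
  n_tok <- length(tok_feats)
  per_tok <- lengths(tok_feats)
  cols <- feat_index[unlist(tok_feats, use.names = FALSE)]
  rows <- rep(seq_len(n_tok), per_tok)
  keep <- !is.na(cols)
  X <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = 1,
                            dims = c(n_tok, length(feat_index)))
  sent_len <- vapply(tagged, function(p) nrow(p$sentence), integer(1))
  y <- unlist(lapply(tagged, function(p) match(p$tags, BIO_TAGS)),
              use.names = FALSE)
  list(X = X, y = y, sent_len = sent_len, feat_index = feat_index)
}

log_sum_exp <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }

# Joint NLL and gradient of a linear-chain CRF. par packs the emission
# weight matrix W (n_feat x K) followed by transitions ((K+1) x K; the extra
# row scores the start transition).
crf_nll_grad <- function(par, des, l1, l2) {
  K <- length(BIO_TAGS)
  nf <- length(des$feat_index)
  W <- matrix(par[seq_len(nf * K)], nf, K)
  Tr <- matrix(par[nf * K + seq_len((K + 1L) * K)], K + 1L, K)
  E <- as.matrix(des$X %*% W)   # token emission scores
  nll <- 0
  Mg <- matrix(0, nrow(E), K)   # posterior marginals - observed
  dTr <- matrix(0, K + 1L, K)
  offset <- 0L
  for (L in des$sent_len) {
    idx <- offset + seq_len(L)
    Es <- E[idx, , drop = FALSE]
    ys <- des$y[idx]
    # forward
    a <- matrix(0, L, K)
    a[1L, ] <- Es[1L, ] + Tr[K + 1L, ]
    if (L > 1L) for (t in 2:L) {
      v <- a[t - 1L, ] + Tr[1:K, , drop = FALSE]      # K x K: v[j,k]
      a[t, ] <- Es[t, ] + apply(v, 2L, log_sum_exp)
    }
    logZ <- log_sum_exp(a[L, ])
    # backward
    b <- matrix(0, L, K)
    if (L > 1L) for (t in (L - 1L):1L) {
      v <- sweep(Tr[1:K, , drop = FALSE], 2L, Es[t + 1L, ] + b[t + 1L, ], "+")
      b[t, ] <- apply(v, 1L, log_sum_exp)
    }
    # gold score
    gold <- Tr[K + 1L, ys[1L]] + Es[cbind(1L, ys[1L])]
    if (L > 1L) gold <- gold + sum(Tr[cbind(ys[-L], ys[-1L])]) +
        sum(Es[cbind(2:L, ys[-1L])])
    nll <- nll + (logZ - gold)
    # unary marginals minus observed
    Mloc <- exp(a + b - logZ)
    Mloc[cbind(seq_len(L), ys)] <- Mloc[cbind(seq_len(L), ys)] - 1
    Mg[idx, ] <- Mloc
    # transition expectations minus observed
    dTr[K + 1L, ] <- dTr[K + 1L, ] + exp(a[1L, ] + b[1L, ] - logZ)
    dTr[K + 1L, ys[1L]] <- dTr[K + 1L, ys[1L]] - 1
    if (L > 1L) for (t in seq_len(L - 1L)) {
      P <- exp(outer(a[t, ], Es[t + 1L, ] + b[t + 1L, ], "+") +
                 Tr[1:K, , drop = FALSE] - logZ)
      P[ys[t], ys[t + 1L]] <- P[ys[t], ys[t + 1L]] - 1
      dTr[1:K, ] <- dTr[1:K, ] + P
    }
    offset <- offset + L
  }
  dW <- as.matrix(Matrix::crossprod(des$X, Mg))
  g <- c(dW, dTr)
  eps <- 1e-8
  pen <- l2 * sum(par^2) + l1 * sum(sqrt(par^2 + eps))
  gpen <- 2 * l2 * par + l1 * par / sqrt(par^2 + eps)
  list(value = nll + pen, grad = g + gpen)
}

#' Train a CRF span detector
#'
#' Fits emission and transition weights by L-BFGS on the exact conditional
#' log-likelihood with an elastic-net penalty. Training is deterministic
#' given the corpus order and penalties (initialization is all-zero).
#'
#' @param tagged tagged corpus from [corpus_to_tagged()].
#' @param l1,l2 regularization penalties.
#' @param max_iter optimizer iteration cap.
#' @return Object of class `ortg_crf` with `predict` support via
#'   [crf_predict()].
#' @export
crf_train <- function(tagged, l1 = 0.1, l2 = 0.1, max_iter = 200L) {
  if (!length(tagged)) stop("empty corpus")
  des <- crf_design(tagged)
  K <- length(BIO_TAGS)
  npar <- length(des$feat_index) * K + (K + 1L) * K
  cache <- new.env(parent = emptyenv())
  fg <- function(par) {
    key <- par
    if (!is.null(cache$par) && identical(cache$par, key)) return(cache$res)
    res <- crf_nll_grad(par, des, l1, l2)
    cache$par <- key; cache$res <- res
    res
  }
  opt <- stats::optim(rep(0, npar), fn = function(p) fg(p)$value,
                      gr = function(p) fg(p)$grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e7))
  W <- matrix(opt$par[seq_len(length(des$feat_index) * K)],
              length(des$feat_index), K)
  Tr <- matrix(opt$par[length(des$feat_index) * K + seq_len((K + 1L) * K)],
               K + 1L, K)
  structure(list(W = W, Tr = Tr, feat_index = des$feat_index,
                 l1 = l1, l2 = l2, nll = opt$value,
                 converged = opt$convergence == 0L),
            class = "ortg_crf")
}

#' @export
print.ortg_crf <- function(x, ...) {
  cat("<CRF span detector: ", length(x$feat_index), " features, l1=", x$l1,
      ", l2=", x$l2, ">\n", sep = "")
  invisible(x)
}

#' Predict BIO(-) tag sequences with a trained CRF
#'
#' Viterbi decoding; features unseen in training are silently dropped, so
#' any sentence is taggable. Prediction length always equals the sentence
#' length and only tags in `{B, I, O, O-}` are emitted.
#'
#' @param model an `ortg_crf` from [crf_train()].
#' @param sentences list of [sentence()] objects.
#' @return List of character tag vectors, one per sentence.
#' @export
crf_predict <- function(model, sentences) {
  if (!length(sentences)) return(list())
  K <- length(BIO_TAGS)
  lapply(sentences, function(sent) {
    L <- nrow(sent)
    E <- matrix(0, L, K)
    for (i in seq_len(L)) {
      f <- model$feat_index[extract_features(sent, i)]
      f <- f[!is.na(f)]
      if (length(f)) E[i, ] <- colSums(model$W[f, , drop = FALSE])
    }
    delta <- matrix(-Inf, L, K)
    back <- matrix(0L, L, K)
    delta[1L, ] <- E[1L, ] + model$Tr[K + 1L, ]
    if (L > 1L) for (t in 2:L) {
      v <- delta[t - 1L, ] + model$Tr[1:K, , drop = FALSE]
      back[t, ] <- apply(v, 2L, which.max)
      delta[t, ] <- E[t, ] + apply(v, 2L, max)
    }
    path <- integer(L)
    path[L] <- which.max(delta[L, ])
    if (L > 1L) for (t in (L - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
    BIO_TAGS[path]
  })
}

#' Randomized search of the L1/L2 penalty space
#'
#' Draws `n_candidates` (l1, l2) pairs from a log-uniform distribution over
#' `[1e-4, 1]` per axis (seeded), scores each by k-fold cross-validated tag
#' F1 on the tuning folds, and returns the best pair with a per-candidate
#' report (l1, l2, macro F1, micro F1).
#'
#' @param tagged tagged corpus.
#' @param config a [crf_config()].
#' @return List `l1`, `l2`, `report` (data frame ordered as sampled),
#'   `best` (row index of the winner).
#' @export
crf_tune <- function(tagged, config = crf_config()) {
  if (length(tagged) < config$cv_folds_tuning)
    stop("need at least ", config$cv_folds_tuning, " sentences to tune")
  if (length(unique(unlist(lapply(tagged, `[[`, "tags")))) < 2L)
    stop("corpus has a single tag class; tuning is meaningless - skip it")
  set.seed(config$seed)
  cand <- data.frame(l1 = 10^runif(config$n_candidates, -4, 0),
                     l2 = 10^runif(config$n_candidates, -4, 0))
  folds <- fold_assign(length(tagged), config$cv_folds_tuning)
  macro <- micro <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    gold <- pred <- character()
    for (k in seq_len(config$cv_folds_tuning)) {
      tr <- tagged[folds != k]; te <- tagged[folds == k]
      mod <- crf_train(tr, cand$l1[i], cand$l2[i], max_iter = config$max_iter)
      p <- crf_predict(mod, lapply(te, `[[`, "sentence"))
      gold <- c(gold, unlist(lapply(te, `[[`, "tags")))
      pred <- c(pred, unlist(p))
    }
    macro[i] <- tag_f1(gold, pred, "macro", include_o = config$include_o)
    micro[i] <- tag_f1(gold, pred, "micro", include_o = config$include_o)
  }
  report <- cbind(cand, f1_macro = macro, f1_micro = micro)
  score <- if (config$objective == "macro") macro else micro
  best <- which.max(score)
  list(l1 = cand$l1[best], l2 = cand$l2[best], report = report, best = best)
}

fold_assign <- function(n, k) {
  # deterministic given the RNG state at the call site
  sample(rep(seq_len(k), length.out = n))
}

#' Cross-validated evaluation of a CRF span detector
#'
#' Trains on k-1 folds and predicts the held-out fold, pooling predictions
#' across folds; reports token-level tag F1 and mention-level exact-match
#' precision/recall/F1 (via [bio_decode()] and [evaluate_spans()]).
#'
#' @param tagged tagged corpus.
#' @param l1,l2 penalties (typically from [crf_tune()]).
#' @param folds number of folds.
#' @param seed RNG seed for fold assignment.
#' @param max_iter optimizer iteration cap per fold.
#' @return List: `mention_f1`, `mention_precision`, `mention_recall`,
#'   `tag_f1_macro`, `tag_f1_micro`, and the pooled predictions.
#' @export
crf_evaluate <- function(tagged, l1, l2, folds = 5L, seed = 1L,
                         max_iter = 200L) {
  set.seed(seed)
  fa <- fold_assign(length(tagged), folds)
  gold_tags <- pred_tags <- character()
  gold_m <- pred_m <- list()
  predictions <- vector("list", length(tagged))
  for (k in seq_len(folds)) {
    tr <- tagged[fa != k]
    te_idx <- which(fa == k)
    mod <- crf_train(tr, l1, l2, max_iter = max_iter)
    p <- crf_predict(mod, lapply(tagged[te_idx], `[[`, "sentence"))
    for (j in seq_along(te_idx)) {
      item <- tagged[[te_idx[j]]]
      predictions[[te_idx[j]]] <- p[[j]]
      gold_tags <- c(gold_tags, item$tags)
      pred_tags <- c(pred_tags, p[[j]])
      gm <- bio_decode(item$sentence, item$tags)
      pm <- bio_decode(item$sentence, p[[j]])
      sid <- paste0("s", te_idx[j])
      gold_m <- c(gold_m, lapply(gm, function(m) { m$doc_id <- sid; m }))
      pred_m <- c(pred_m, lapply(pm, function(m) { m$doc_id <- sid; m }))
    }
  }
  sp <- evaluate_spans(gold_m, pred_m, mode = "exact")
  list(mention_f1 = sp$f1, mention_precision = sp$precision,
       mention_recall = sp$recall,
       tag_f1_macro = tag_f1(gold_tags, pred_tags, "macro", include_o = FALSE),
       tag_f1_micro = tag_f1(gold_tags, pred_tags, "micro", include_o = FALSE),
       predictions = predictions)
}

#' Rule-of-thumb hidden-unit count for a recurrent span detector
#'
#' `N_h = N_s / (alpha * (N_i + N_o))`, rounded, floored at 1: the training
#' sample count divided by a scaling factor (conventionally 2-10) times the
#' total input and output neuron count.
#'
#' @param n_samples training sample count.
#' @param n_input input neuron count.
#' @param n_output output neuron count.
#' @param alpha scaling factor in `[2, 10]`.
#' @return Integer >= 1.
#' @export
compute_hidden_units <- function(n_samples, n_input, n_output, alpha = 2) {
  if (any(c(n_samples, n_input, n_output, alpha) <= 0))
    stop("all arguments must be positive")
  max(1L, as.integer(round(n_samples / (alpha * (n_input + n_output)))))
}
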