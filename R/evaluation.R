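# Measurement suite: class-ID exact match, character-level fractional match,
# non-existent-ID rate, seen/unseen breakdown, and span precision/recall/F1
# under exact and Jaccard-partial matching. The span metric is an internal,
# non-official surrogate for shared-task scorers: plain character-set Jaccard
# with no ontology-hierarchy credit.

#' Character-level partial-match score between two class identifiers
#'
#' Positional character matches over the aligned prefix of the two strings,
#' divided by the length of the longer string, so both over- and
#' under-generation are penalized symmetrically. Equal-length identifiers
#' differing in one character of twelve score 11/12.
#'
#' @param gold_id gold class identifier (non-empty).
#' @param pred_id predicted class identifier (non-empty).
#' @return Fraction in `[0, 1]`; 1 iff the strings are identical.
#' @export
char_level_score <- function(gold_id, pred_id) {
  if (!nzchar(gold_id) || !nzchar(pred_id)) stop("empty identifier")
  g <- strsplit(gold_id, "", fixed = TRUE)[[1]]
  p <- strsplit(pred_id, "", fixed = TRUE)[[1]]
  n <- min(length(g), length(p))
  sum(g[seq_len(n)] == p[seq_len(n)]) / max(length(g), length(p))
}

#' Evaluate concept-normalization predictions
#'
#' Computes, over aligned gold/predicted identifier pairs: the class-ID
#' exact-match percentage, the mean character-level score (as a percentage),
#' the percentage of mismatched predictions that are non-existent identifiers
#' (absent from the ontology vocabulary), and the abstention (false-negative)
#' percentage for dictionary-style predictors that return `NA`. Given the
#' training mention set, the same fields are reported separately for mentions
#' seen and unseen in training (exact, case-sensitive string membership).
#'
#' Abstentions count as misses at both levels (character score 0) and are
#' excluded from the non-existent-ID denominator, which covers predicted
#' mismatches only.
#'
#' @param gold character vector of gold class ids.
#' @param pred character vector of predicted ids; `NA` = abstained.
#' @param ontology_vocab character vector of all valid class ids.
#' @param mentions mention strings aligned with `gold`/`pred` (needed for the
#'   seen/unseen split; optional otherwise).
#' @param training_mentions character vector of mention strings present in
#'   the training data.
#' @return List of class `ortg_norm_report`.
#' @export
evaluate_normalization <- function(gold, pred, ontology_vocab = NULL,
                                   mentions = NULL, training_mentions = NULL) {
  if (!length(gold)) stop("empty pair list")
  if (length(gold) != length(pred)) stop("gold/pred length mismatch")
  base <- norm_block(gold, pred, ontology_vocab)
  rep <- c(base, list(n = length(gold)))
  if (!is.null(mentions) && !is.null(training_mentions)) {
    stopifnot(length(mentions) == length(gold))
    seen <- mentions %in% training_mentions
    rep$n_seen <- sum(seen)
    rep$n_unseen <- sum(!seen)
    rep$seen <- if (any(seen)) norm_block(gold[seen], pred[seen], ontology_vocab)
    rep$unseen <- if (any(!seen)) norm_block(gold[!seen], pred[!seen], ontology_vocab)
  }
  structure(rep, class = "ortg_norm_report")
}

norm_block <- function(gold, pred, vocab) {
  abst <- is.na(pred)
  exact <- !abst & gold == pred
  charscore <- ifelse(abst, 0,
                      mapply(function(g, p) if (is.na(p)) 0 else char_level_score(g, p),
                             gold, pred))
  mism <- !abst & !exact
  pct_nonexistent <- if (!is.null(vocab) && any(mism))
    100 * mean(!(pred[mism] %in% vocab)) else if (!is.null(vocab)) 0 else NA_real_
  list(pct_class_id_exact = 100 * mean(exact),
       pct_character = 100 * mean(charscore),
       pct_nonexistent_of_mismatches = pct_nonexistent,
       pct_false_negative = 100 * mean(abst))
}

#' @export
print.ortg_norm_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat("Concept normalization report (n = ", x$n, ")\n", sep = "")
  cat("  class-ID exact:      ", fmt(x$pct_class_id_exact), "\n")
  cat("  character level:     ", fmt(x$pct_character), "\n")
  cat("  non-existent of mism:", fmt(x$pct_nonexistent_of_mismatches), "\n")
  cat("  abstained (FN):      ", fmt(x$pct_false_negative), "\n")
  for (side in c("seen", "unseen")) {
    if (!is.null(x[[side]]))
      cat(sprintf("  %-6s (n=%d): exact %s, char %s\n", side,
                  x[[paste0("n_", side)]],
                  fmt(x[[side]]$pct_class_id_exact),
                  fmt(x[[side]]$pct_character)))
  }
  invisible(x)
}

mention_char_set <- function(m) {
  key <- m$doc_id %||% ""
  unlist(lapply(m$spans, function(s) paste0(key, ":", seq(s[1L], s[2L] - 1L))))
}

mention_key <- function(m) {
  paste0(m$doc_id %||% "", "|",
         paste(vapply(m$spans, function(s) paste0(s[1L], "-", s[2L]),
                      character(1)), collapse = ";"))
}

#' Span-detection precision/recall/F1 (non-official internal metric)
#'
#' Exact mode: one-to-one matching on identical (document, span-set) keys.
#' Jaccard mode: greedy one-to-one matching by descending character-set
#' Jaccard index; each matched pair contributes its Jaccard value as
#' fractional true-positive credit, unmatched gold mentions are false
#' negatives and unmatched predictions false positives. Discontinuous
#' mentions use the union of their spans' characters. This surrogate awards
#' no ontology-semantic-similarity credit and is not comparable to official
#' shared-task scorers.
#'
#' @param gold,pred lists of [mention()] objects (doc_id-aware).
#' @param mode `"exact"` or `"jaccard"`.
#' @return List of class `ortg_span_report`: `precision`, `recall`, `f1`,
#'   `mode`, counts. Degenerate denominators report 0.
#' @export
evaluate_spans <- function(gold, pred, mode = c("exact", "jaccard")) {
  mode <- match.arg(mode)
  ng <- length(gold); np <- length(pred)
  if (mode == "exact") {
    gk <- vapply(gold, mention_key, character(1))
    pk <- vapply(pred, mention_key, character(1))
    tp <- 0
    avail <- pk
    for (k in gk) {
      hit <- match(k, avail)
      if (!is.na(hit)) { tp <- tp + 1; avail <- avail[-hit] }
    }
  } else {
    gsets <- lapply(gold, mention_char_set)
    psets <- lapply(pred, mention_char_set)
    jacc <- matrix(0, ng, np)
    for (i in seq_len(ng)) for (j in seq_len(np)) {
      inter <- length(intersect(gsets[[i]], psets[[j]]))
      if (inter > 0)
        jacc[i, j] <- inter / length(union(gsets[[i]], psets[[j]]))
    }
    tp <- 0
    while (ng > 0 && np > 0 && length(jacc) && max(jacc) > 0) {
      best <- which(jacc == max(jacc), arr.ind = TRUE)[1L, ]
      tp <- tp + jacc[best[1L], best[2L]]
      jacc[best[1L], ] <- -1
      jacc[, best[2L]] <- -1
    }
  }
  precision <- if (np > 0) tp / np else 0
  recall <- if (ng > 0) tp / ng else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1, mode = mode,
                 n_gold = ng, n_pred = np, tp = tp),
            class = "ortg_span_report")
}

#' @export
print.ortg_span_report <- function(x, ...) {
  cat(sprintf("Span report (%s, non-official): P=%.3f R=%.3f F1=%.3f (gold %d, pred %d)\n",
              x$mode, x$precision, x$recall, x$f1, x$n_gold, x$n_pred))
  invisible(x)
}

#' Token-level tag F1
#'
#' Per-tag F1 from the confusion counts, aggregated as a macro (unweighted
#' mean over tags) or micro (pooled counts) average. The dominant O tag can
#' be excluded so the score reflects mention structure rather than outside
#' text.
#'
#' @param gold_tags,pred_tags aligned character vectors of tags.
#' @param averaging `"macro"` or `"micro"`.
#' @param include_o include the `O` tag?
#' @return F1 in `[0, 1]`.
#' @export
tag_f1 <- function(gold_tags, pred_tags, averaging = c("macro", "micro"),
                   include_o = TRUE) {
  averaging <- match.arg(averaging)
  if (length(gold_tags) != length(pred_tags)) stop("tag sequence length mismatch")
  classes <- if (include_o) BIO_TAGS else setdiff(BIO_TAGS, "O")
  classes <- intersect(classes, unique(c(gold_tags, pred_tags)))
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    tp[cl] <- sum(gold_tags == cl & pred_tags == cl)
    fp[cl] <- sum(gold_tags != cl & pred_tags == cl)
    fn[cl] <- sum(gold_tags == cl & pred_tags != cl)
  }
  f1_of <- function(tp, fp, fn) {
    denom <- 2 * tp + fp + fn
    ifelse(denom > 0, 2 * tp / denom, 0)
  }
  if (averaging == "micro") {
    f1_of(sum(tp), sum(fp), sum(fn))
  } else {
    present <- tp + fn > 0   # macro over tags that occur in the gold
    if (!any(present)) return(0)
    mean(f1_of(tp[present], fp[present], fn[present]))
  }
}
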