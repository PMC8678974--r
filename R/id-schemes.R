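# Class-identifier transformations probing whether identifiers carry
# exploitable structure: shuffling the mention-to-id relationship, replacing
# ids with fresh random digit strings, and assigning consecutive ids in
# mention-alphabetical order. All schemes keep the namespace prefix and only
# change the numeric local part; textual local ids (e.g. a taxonomic-rank
# name) are fixed points everywhere.

id_local <- function(id) sub("^[^:]*:", "", id)
id_ns <- function(id) sub(":.*$", "", id)
is_numeric_local <- function(id) grepl("^[0-9]+$", id_local(id))

new_id_mapping <- function(scheme, forward, seed = NA_integer_) {
  if (anyDuplicated(forward))
    stop("id mapping is not injective")
  structure(list(scheme = scheme, forward = forward, seed = seed),
            class = "ortg_id_mapping")
}

#' @export
print.ortg_id_mapping <- function(x, ...) {
  cat("<id mapping: ", x$scheme, ", ", length(x$forward), " keys>\n", sep = "")
  invisible(x)
}

#' Shuffled identifiers: permute the id set over the classes
#'
#' Applies a seeded permutation of the numeric-local-id set onto itself, so
#' the multiset of identifiers is preserved but the relationship between
#' mention and identifier is scrambled. Identifiers with textual local parts
#' map to themselves.
#'
#' @param ontology_ids character vector of class ids.
#' @param seed RNG seed.
#' @return An id mapping (`forward`: named character vector keyed by
#'   original class id).
#' @export
shuffled_ids <- function(ontology_ids, seed = 1L) {
  num <- ontology_ids[is_numeric_local(ontology_ids)]
  if (!length(num)) stop("need at least one numeric-id class")
  set.seed(seed)
  fwd <- setNames(ontology_ids, ontology_ids)
  fwd[num] <- num[sample(length(num))]
  new_id_mapping("shuffled", fwd, seed)
}

#' Random identifiers: fresh digit strings of identical length
#'
#' Each numeric local id is replaced by a uniformly drawn digit string of the
#' same length, drawn without replacement so no two classes collide; the
#' namespace is preserved and textual ids are fixed points. Variable-length
#' ids (one to many digits) keep their lengths.
#'
#' @inheritParams shuffled_ids
#' @return An id mapping.
#' @export
random_ids <- function(ontology_ids, seed = 1L) {
  num <- ontology_ids[is_numeric_local(ontology_ids)]
  if (!length(num)) stop("need at least one numeric-id class")
  set.seed(seed)
  fwd <- setNames(ontology_ids, ontology_ids)
  lens <- nchar(id_local(num))
  for (L in unique(lens)) {
    ids <- num[lens == L]
    space <- 10^L
    if (length(ids) > space)
      stop("more classes (", length(ids), ") than ", L, "-digit strings")
    if (space <= 1e6) {
      draws <- sample.int(space, length(ids)) - 1L
    } else {
      draws <- unique(floor(runif(length(ids) * 2) * space))
      while (length(draws) < length(ids))
        draws <- unique(c(draws, floor(runif(length(ids)) * space)))
      draws <- draws[seq_along(ids)]
    }
    fwd[ids] <- paste0(id_ns(ids), ":",
                       formatC(draws, width = L, flag = "0", format = "d"))
  }
  new_id_mapping("random", fwd, seed)
}

#' Alphabetical identifiers: consecutive ids in mention sort order
#'
#' Mentions are sorted in plain code-point order and the i-th mention maps to
#' `namespace:i` zero-padded to `width`, so lexicographically adjacent
#' mentions receive numerically consecutive identifiers. Every distinct
#' mention gets its own id, even mentions annotated with the same gold class;
#' under this scheme the mapping key is therefore the mention string, and
#' the per-mention alphabetical id is the gold evaluation target.
#'
#' @param unique_mentions character vector of distinct mention strings.
#' @param namespace namespace prefix for the generated ids.
#' @param width digit width; default the wider of 5 and the digits needed.
#' @return An id mapping keyed by mention string.
#' @export
alphabetical_ids <- function(unique_mentions, namespace,
                             width = max(5L, nchar(length(unique_mentions)))) {
  if (anyDuplicated(unique_mentions)) stop("mentions must be unique")
  if (10^width - 1 < length(unique_mentions))
    stop("width ", width, " too small for ", length(unique_mentions), " mentions")
  sorted <- sort(unique_mentions, method = "radix")
  fwd <- setNames(paste0(namespace, ":",
                         formatC(seq_along(sorted), width = width, flag = "0",
                                 format = "d")),
                  sorted)
  new_id_mapping("alphabetical", fwd)
}

#' Apply an id mapping to a training set
#'
#' Rewrites targets through the mapping. For class-keyed schemes (shuffled,
#' random, identity) the key is the pair's target id; for the alphabetical
#' scheme the key is the pair's mention string, so same-class mentions
#' diverge to distinct targets. Every key must be covered.
#'
#' @param ts a training set.
#' @param m an id mapping.
#' @return The training set with rewritten targets (re-aggregated if the
#'   rewrite merges pairs).
#' @export
apply_id_mapping <- function(ts, m) {
  key <- if (m$scheme == "alphabetical") ts$pairs$source else ts$pairs$target
  miss <- setdiff(unique(key), names(m$forward))
  if (length(miss))
    stop("mapping does not cover key(s): ", paste(head(miss, 3), collapse = ", "))
  ts$pairs$target <- unname(m$forward[key])
  agg <- stats::aggregate(weight ~ source + target, data = ts$pairs, FUN = sum)
  ts$pairs <- data.frame(source = agg$source, target = agg$target,
                         weight = if (ts$level == "token") agg$weight else 1,
                         origin = "corpus-annotation", stringsAsFactors = FALSE)
  ts
}

#' Identity mapping over a key set
#'
#' @param keys character vector.
#' @return An id mapping sending every key to itself.
#' @export
identity_ids <- function(keys) {
  new_id_mapping("identity", setNames(keys, keys))
}

#' Serialize / load an id mapping as two-column TSV for audit
#'
#' @param m an id mapping.
#' @param path file path.
#' @export
write_id_mapping <- function(m, path) {
  writeLines(c(paste0("# scheme: ", m$scheme),
               paste(names(m$forward), m$forward, sep = "\t")), path)
  invisible(path)
}

#' @rdname write_id_mapping
#' @export
read_id_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  scheme <- sub("^# scheme: ", "", lines[1L])
  parts <- do.call(rbind, strsplit(lines[-1L], "\t", fixed = TRUE))
  new_id_mapping(scheme, setNames(parts[, 2L], parts[, 1L]))
}
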