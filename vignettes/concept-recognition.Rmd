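---
title: "Concept recognition as sequence tagging plus character-level translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept recognition as sequence tagging plus character-level translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical text refers to ontology concepts — cell types, chemical
entities, biological processes — through highly variable surface forms:
`GO:0005886` may appear as "plasma membrane", "cell membrane" or
"plasmalemma". Recognizing these references involves two tasks that this
package treats separately, as most shared-task evaluations do:

* **span detection** — delimiting the text region of a mention, including
  the awkward cases: *discontinuous* mentions ("red … blood cells" inside
  "red and white blood cells") and *overlapping* mentions sharing tokens;
* **concept normalization** — mapping each detected mention to one class
  identifier such as `CL:0000738`.

Treating normalization as a classification problem over the tens of
thousands of classes of an Open Biomedical Ontology is impractical. The
approach implemented here instead treats it as **character-level sequence
translation**: the mention's characters are the source sequence, the class
identifier's characters (`C L : 0 0 0 0 7 3 8`) are the target sequence,
and a small attention encoder–decoder learns the mapping. Surprisingly,
this works — in part because curated identifiers are not as arbitrary as
their design principles claim, a point probed directly by the
identifier-scheme experiments below.

## The BIO(−) tag scheme

Span detection is sequence tagging over tokens with four labels. `B` marks
the first token of a mention's first span, `I` any other mention token, `O`
outside text, and `O−` — the scheme's extension — tokens lying *between*
the spans of a discontinuous mention. For "red and white blood cells"
carrying the mentions *red … blood cells* and *white blood cells*:

| red | and | white | blood | cells |
|-----|-----|-------|-------|-------|
| B   | O−  | B     | I     | I     |

Overlap conflicts resolve by the precedence **B > I > O− > O**: beginnings
are preserved even at the cost of truncating another mention's tail, so
each tag sequence is deterministic regardless of annotation order. Decoding
inverts the scheme: a `B I*` run is a span; an `O−` run holds the preceding
mention open, and a following `I`-run becomes its second span, while a
following `B` (or `O`, or the sentence end — a case the scheme leaves open;
we emit) closes it truncated. With four tags, arbitrary overlapping mention
sets are *not* recoverable; that is an acknowledged limit of the scheme,
not a bug. Round-trip identity holds for continuous non-overlapping
mentions and isolated discontinuous mentions, and is property-tested.

Mention spans that do not align with token boundaries are snapped outward
to the covering tokens with a warning; mentions crossing sentence
boundaries are dropped with a warning, since every sequence model here is
sentence-scoped.

## The CRF span detector

The detector is a linear-chain conditional random field written from first
principles (exact forward–backward gradients, Viterbi decoding), since the
feature template and the tuning procedure are the scientifically meaningful
parts. Features per token: the lowercased word identity, its case shape
(all-lower / all-upper / initial-cap / mixed / non-alpha), the three
preceding word identities, the token's POS tag, and the POS tags of the two
following tokens, with `<s>` / `</s>` sentinels beyond sentence bounds.

Training maximizes the penalized conditional log-likelihood by L-BFGS with
an elastic-net penalty; the L1 term is smoothed as `sqrt(x^2 + 1e-8)` so a
quasi-Newton method applies. Hyperparameter search draws `n_candidates`
(default 50) L1/L2 pairs from a log-uniform distribution over `[1e-4, 1]`
per axis — reported optima for this kind of model span about three decades,
which that range covers — and scores each by 3-fold cross-validated tag F1.
The default tuning objective is **macro-F1 over {B, I, O−}**: the `O` tag
dominates any corpus, so micro-averaged F1 saturates near 1 and hides all
mention structure. Final quality is measured by 5-fold cross-validation at
the mention level (decode, then exact-match P/R/F1).

Other sequence taggers (recurrent or transformer-based) are deliberately
out of scope, but anything honoring the `crf_predict()` contract — one tag
sequence per sentence, same lengths — can be evaluated by the same
machinery. For sizing such models, `compute_hidden_units()` implements the
standard rule of thumb `N_h = N_s / (alpha * (N_i + N_o))` with
`alpha` in [2, 10], rounded and floored at 1.

POS tags: gold tags are used whenever the input provides them (the
synthetic generator always does). The fallback is a small deterministic
rule tagger (`rule_pos_tagger()`); it is crude, but the CRF only consumes
tags as categorical context features, and any `function(words) -> tags`
can be plugged in.

## The translation normalizer

Training pairs are (mention text, class id) from corpus annotations,
assembled at the **token level** (distinct pairs weighted by occurrence
count — frequency matters downstream) or the **type level** (each distinct
pair once). Both levels contain the same distinct pairs by construction.
With augmentation on, every ontology class absent from the corpus
contributes its primary label and each exact synonym as quasi-mentions, so
the model covers the whole ontology; curated exclusion lists are honored.

Text and identifiers are encoded one character per token, with the
inter-word space an explicit `<sp>` symbol — so "white blood cell" is 16
tokens, `CL:0000738` is 10 — and sequences are end-padded with `<pad>` to
the longest training length. Mention text is used verbatim (no case
folding); the dictionary baseline folds case by default; both are switches.

The network is a single-layer bidirectional tanh-RNN encoder and a
single-layer decoder with global multiplicative attention, trained with
teacher forcing, Adam, global-norm gradient clipping, and a seeded 90–10
train/validation split tracked per epoch. Defaults: embedding 32, hidden 64
per direction, batch 32, learning rate 0.005, 400 epochs. These are desk
scale on purpose: the contribution is the framing, not the parameter count,
and one recurrent layer memorizes and generalizes indistinguishably from a
deeper stack at fixture sizes while keeping the hand-derived backprop —
which is verified against finite differences in the test suite — auditable.
Decoding is greedy, and the translator **never abstains**: every input
yields an identifier string, existent or not. That contract is exactly what
separates it from the dictionary baseline (`dictionary_baseline()`), an
exact-lookup predictor that returns no answer for unseen mentions and
whose misses are therefore counted as false negatives.

Padded batches use masked state updates in the encoder (padded positions
leave the hidden state unchanged, and attention is masked to content
positions), so batch composition does not alter per-pair computations.
Duplicate-aware splitting is resolved by splitting over distinct pairs
(weights ride along); how token-level duplicates should straddle a
validation split is genuinely underdetermined, and this choice keeps the
split leak-free.

## Identifier-scheme experiments

Do class identifiers carry signal a translator can exploit? Three seeded,
injective transformations of the training targets probe this:

* **shuffled-ids** — permute the existing numeric ids among the classes:
  the id multiset survives, the mention-to-id relationship is scrambled;
* **random-ids** — replace each numeric local id by a fresh uniform digit
  string of the same length, drawn without replacement;
* **alphabetical-ids** — sort the distinct mentions and assign consecutive
  zero-padded ids (width at least 5) in sort order, one id per mention even
  when mentions share a gold class — so under this scheme gold targets are
  per-mention.

Namespace prefixes are always preserved and textual local ids (e.g.
`NCBITaxon:species`) are fixed points in every scheme. The shuffle
permutes ids across classes (the natural reading of scrambling the
relationship); permuting across mention–id pairs instead would only differ
for multi-mention classes.

`scheme_experiment()` runs the comparison end to end: type-level pairs,
each scheme trained under a fixed budget, seen-mention exact match
measured, repeated over seeds. On an id-clustered synthetic ontology the
expected ordering of means is `identity >= shuffled >= random`: clustering
lets related mentions share id prefixes (compositional, learnable),
shuffling destroys that locality but keeps the digit distribution, and
random ids additionally maximize target entropy. The experiment uses a
fixed 250-epoch budget — a near-convergence regime chosen because the
effect is a *learnability* difference: train to saturation and every scheme
memorizes a toy set; stop far earlier and noise dominates.

## Evaluation metrics

* **Class-id exact match** — the percentage of predictions identical to
  gold.
* **Character-level match** — positional agreement over the aligned prefix
  divided by the longer length, averaged; a one-digit miss on a 12-character
  identifier scores 11/12 ≈ 0.92. The denominator choice (max of the two
  lengths) is ours: the worked example has equal lengths and does not
  disambiguate, and max penalizes over- and under-generation symmetrically.
* **Non-existent-id rate** — among predicted mismatches, the share of
  identifiers absent from the ontology vocabulary; a proxy for whether the
  translator stays "in vocab".
* **Seen/unseen breakdown** — all of the above split by exact,
  case-sensitive membership of the mention string in the training mentions.
* **Span P/R/F1** — exact span-set matching, and a Jaccard-partial mode in
  which greedily matched pairs earn their character-set Jaccard index as
  fractional credit (discontinuous mentions use the union of their spans'
  characters). Partial credit never hurts: Jaccard-mode F1 is bounded below
  by exact-mode F1. This metric is **non-official**: it awards no
  ontology-semantic-similarity credit and is not comparable to shared-task
  scorers.
* **Token-level tag F1** — macro or micro, with the dominant `O` tag
  excludable for the reason given above.

## The synthetic study conditions

`fixture_config()` + `generate_ontology()` + `generate_corpus()` produce
the conditions every quality claim in the test suite is measured under:

* labels are "modifier head" two-word phrases over a fixed vocabulary, with
  plural and hyphenated exact synonyms; a configurable fraction of classes
  reserve the hyphenated synonym for evaluation documents (held-out
  synonyms, the generalization probe);
* mention frequencies follow a Zipf law (exponent configurable), so token-
  and type-level sets genuinely differ;
* a configurable fraction of mentions are conjunction ellipses
  ("red and white cells") yielding one discontinuous mention overlapping a
  continuous one — the canonical hard case — and another fraction nests a
  single-head mention inside a multi-word one;
* with id clustering on, each head-word group occupies a block of
  sequentially adjacent ids placed at a seeded position within its segment
  of the digit space. Curated ontologies look like this — related classes
  adjacent (`PR:000004803`/`PR:000004804`), the id set sparse in the space —
  and the layout matters: with dense sequential ids all schemes share a
  near-constant prefix and the scheme experiments lose their subject.
* filler vocabulary is disjoint from mention vocabulary by default, making
  the CRF task separable; gold POS tags come from a fixed table.

What the generator does **not** emulate: real morphological variation,
ambiguity of mention words with ordinary text (switchable but off), long
acronym-laden mentions, and ontology-scale class counts. Passing tests on
these fixtures therefore demonstrate mechanism correctness and qualitative
behavior, not corpus-scale performance numbers.

Problem sizes used by the test suite (the package's choices for a laptop-
class run): 200-sentence corpora for the 5-fold CRF evaluation, 30–50
distinct pairs for memorization checks at 400–500 epochs, and 30 classes ×
3 seeds × 250 epochs for the scheme experiment.

## Numerical and degenerate-input choices

* CRF optimization starts from zero weights, so training is deterministic
  given corpus order and penalties; tie-breaks in tuning take the first
  best candidate in sampling order.
* Empty sentences, empty corpora and single-tag corpora raise informative
  errors rather than degenerate fits; all-`O` training yields an all-`O`
  predictor.
* Greedy decoding that immediately emits the end symbol is forced to the
  best non-special symbol, honoring the never-abstain contract.
* Span metric denominators of zero (no predictions, no gold) report 0.
* All randomness — candidate sampling, fold assignment, initialization,
  batch order, the 90–10 split, every generator — flows from explicit seeds.

## A worked end-to-end example

```{r, eval = FALSE}
library(ontorecog)

cfg <- fixture_config(n_classes = 10, n_docs = 8, mentions_per_doc = 5,
                      zipf_exponent = 0.5, seed = 21)
ont <- generate_ontology(cfg)
pcfg <- pipeline_config(generate_corpus(ont, cfg, "train"),
                        generate_corpus(ont, cfg, "eval"), ont,
                        crf = crf_config(l1 = 0.05, l2 = 0.05),
                        norm = normalizer_config(epochs = 400),
                        augment = FALSE, seed = 1)
res <- run_pipeline(pcfg, out_dir = "toy-run")
res
```

The result prints the non-official span P/R/F1 under exact and Jaccard
matching and the normalization percentages; `toy-run/` holds the models,
predicted standoff files, reports and a manifest recording seeds and
configuration.

## Known limitations

* Arbitrarily overlapping mention sets cannot be represented in four tags;
  the encoder keeps beginnings and truncates the rest by design.
* The span metric is an internal surrogate; absolute values are not
  comparable to official shared-task scores.
* Beam search, subword vocabularies, stacked recurrent layers and
  transformer span detectors are out of scope; the interfaces accommodate
  them, the implementations do not provide them.
* Stemming- or lemmatization-aware alphabetical ids (grouping
  "hybridization"/"hybridizations" before assigning ids) are deliberately
  not implemented.
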