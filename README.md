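# ontorecog

Ontology concept recognition for biomedical text, in two stages:

1. **Span detection** with an extended BIO(−) token tag scheme — `B` begins
   a mention, `I` continues one, `O` is outside text, and `O−` marks tokens
   lying *between* the spans of a discontinuous mention (so "red … blood
   cells" inside "red and white blood cells" is representable). Overlap
   conflicts resolve by the precedence B > I > O− > O. The detector is a
   linear-chain CRF over lexical/shape/POS context features with randomized
   log-uniform L1/L2 search (3-fold CV) and 5-fold mention-level evaluation.
2. **Concept normalization** recast as character-level sequence translation:
   the mention's characters (`w h i t e <sp> b l o o d <sp> c e l l`) are
   translated to the class identifier's characters (`C L : 0 0 0 0 7 3 8`)
   by a small attention encoder–decoder that never abstains, next to an
   exact-lookup dictionary baseline that abstains on anything unseen.

Around the core sit the identifier-scheme experiments (shuffled / random /
alphabetical ids, probing the semantic signal hidden in "arbitrary" class
identifiers), an evaluation suite (class-id exact match, character-level
fractional match `11/12 ≈ 0.92` for a one-digit miss, non-existent-id rate,
seen/unseen breakdown, and a non-official Jaccard-partial span metric),
readers/writers for OBO flat files and brat-style standoff annotations, and
seeded synthetic ontology/corpus generators so the whole pipeline runs end
to end with no external data.

Intended users: biomedical NLP researchers studying concept recognition and
entity linking who need a transparent, dependency-light, fully seeded
reference implementation of the tagging scheme, the translation framing,
and the identifier experiments.

## A worked example

```r
library(ontorecog)

# the canonical discontinuous + overlapping phrase
sent <- sentence(data.frame(
  text = c("red", "and", "white", "blood", "cells"),
  start = c(0L, 4L, 8L, 14L, 20L), end = c(3L, 7L, 13L, 19L, 25L),
  pos = c("JJ", "CC", "JJ", "NN", "NNS")))
men <- list(mention(list(c(0L, 3L), c(14L, 25L)), "CL:0000232"),
            mention(list(c(8L, 25L)), "CL:0000738"))
bio_encode(sent, men)
#> [1] "B"  "O-" "B"  "I"  "I"

char_level_score("PR:000004804", "PR:000004803")
#> [1] 0.9166667
```

The tag sequence says: a mention begins at "red", the tokens "and" sit
between the spans of that (discontinuous) mention, and a second mention
"white blood cells" begins at "white". The score says: a predicted
identifier one digit off from a 12-character gold identifier earns 11/12 of
the credit at the character level.

End to end on synthetic data:

```r
cfg <- fixture_config(n_classes = 10, n_docs = 8, mentions_per_doc = 5,
                      zipf_exponent = 0.5, seed = 21)
ont <- generate_ontology(cfg)
res <- run_pipeline(pipeline_config(
  generate_corpus(ont, cfg, "train"), generate_corpus(ont, cfg, "eval"),
  ont, crf = crf_config(l1 = 0.05, l2 = 0.05),
  norm = normalizer_config(epochs = 400), augment = FALSE, seed = 1),
  quiet = TRUE)
res
#> Pipeline result (TOY)
#>   spans [exact]: P=0.925 R=0.925 F1=0.925
#>   spans [jaccard]: P=0.969 R=0.969 F1=0.969
#>   normalization: class-ID 100.0%, character 100.0%
```

On this easy fixture (disjoint mention/filler vocabulary, memorizable
identifier set) the CRF recovers nearly every span — the Jaccard-partial
score exceeding the exact score shows the residual errors are boundary
slips, not hallucinated mentions — and the translator normalizes every
gold mention; the methods vignette
(`vignettes/concept-recognition.Rmd`) explains what such fixtures do and do
not demonstrate, and documents every tunable parameter.

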