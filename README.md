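# morphgloss

Medical educational text is routinely written above the reading level of
the people it is meant to help. One remedy is to find the *difficult
terms* in a document and attach an easier synonym (lexical
simplification) or a plain-language explanation (semantic
simplification). Curated resources that can supply such explanations —
consumer-health vocabularies, general lexical databases — cover only a
fraction of the difficult terms that actually occur, in English and even
less so in Spanish.

`morphgloss` closes part of that gap by *building* explanations where no
resource has one. Medical terms are largely assembled from Greek and
Latin morphological units with stable meanings (*cardio-* "the heart",
*-itis* "inflammation"), so a term outside every dictionary can still be
glossed unit by unit. The package is aimed at text-simplification
researchers and builders of consumer-health NLP pipelines, and also
implements the supporting study machinery: difficult-term identification
by corpus frequency (term familiarity), balanced stimulus sampling, and
the rating-based evaluation metrics used to compare explanation sources.

## The method

For a normalized term *t* and a language-specific affix dictionary, one
recursion level does:

1. **Affix identification** — match dictionary prefixes against the
   start of *t* and suffixes against the end, always longest form first
   (so *anti-* wins over *a-* in *antihero*), and attach each matched
   affix's plain-language definition. A match must leave a remainder of
   at least `min_root_length` (default 2) characters.
2. **Root lookup** — search the remainder through an ordered cascade of
   lexicon backends (consumer-health lexicon first, then the general
   lexicon), trying the bare remainder, its single-character edge
   variants (boundary character restored, one character dropped), and
   the stemmed form of each (Porter for English, Snowball-style for
   Spanish). A hit makes the remainder a glossed *root* and ends the
   branch.
3. **Recursion** — if the lookup fails but an affix was stripped, the
   remainder re-enters step 1. A remainder with no match and no lookup
   hit becomes *residue*, glossed by itself.

The resulting units concatenate exactly back to the term and are
rendered as an aligned two-line gloss (optionally colour-coded):

```
hyper-glyc-em-ic
denotes something as extreme or beyond normal-sugar-em-pertaining to
```

For evaluating explanation sources over a set of *N* study terms rated
on a 1–4 Likert scale by multiple raters:

* **quality** — mean per-term rating over the terms a source covers
  (1–4 scale);
* **coverage** — fraction of the *N* terms the source covers;
* **usefulness** — mean rating over *all N* terms with 0 substituted
  when the source offers nothing, so `usefulness = quality × coverage`
  exactly;
* **agreement** — conservative (identical best-choice sets) and liberal
  (intersecting best-choice sets) per-term indicators, plus Cronbach's
  alpha with raters as items;
* **cumulative cascade metrics** — coverage by union and usefulness by
  per-term maximum as sources are added to a combined system.

## Worked example

```r
library(morphgloss)

dict     <- builtin_affix_dictionary("en")
backends <- builtin_backends("en")          # chv-style, then wordnet-style

parse_term("hyperglycemic", dict, backends)$units
#>   surface    kind                                    definition           source
#> 1   hyper  prefix denotes something as extreme or beyond normal affix_dictionary
#> 2    glyc  prefix                                         sugar affix_dictionary
#> 3      em residue                                            em       unresolved
#> 4      ic  suffix                                 pertaining to affix_dictionary
```

`hyper-` and the inner units `glyc-` and `-ic` come from the affix
dictionary; `em` matches nothing anywhere, so it is kept as residue and
glossed by itself. When a stripped remainder *is* in a backend, it
becomes a root with that backend's definition:

```r
parse_term("cardiovascular", dict, backends)$units
#>    surface   kind                        definition           source
#> 1   cardio prefix                         the heart affix_dictionary
#> 2 vascular   root consisting of a vessel or vessels          wordnet
```

Metrics from a rating table:

```r
marg <- data.frame(source  = c("chv", "wordnet_summary"),
                   quality = c(2.81, 3.32), covered = c(24, 212))
compute_metrics(ratings_from_marginals(marg, n_terms = 400), 400)
#>            source  quality coverage usefulness
#> 1             chv 2.812500     0.06    0.16875
#> 2 wordnet_summary 3.320755     0.53    1.76000
```

A source that writes excellent definitions but covers 24 of 400 terms
ends up with a usefulness near 0.17 out of 4 — the motivation for
generating explanations for everything else.

A command-line wrapper is provided for shell use:

```sh
echo hyperglycemic | exec/morphgloss explain --language en
```

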