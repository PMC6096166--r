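---
title: "Morphological glossing of difficult medical terms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological glossing of difficult medical terms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphgloss)
```

## The problem and the model

Consumer-health text simplification replaces or annotates *difficult
terms* — terms rare in everyday language — with easier synonyms or
plain-language explanations. Curated lexicons supply high-quality
explanations but cover few medical terms; fully automatic synonym
sources cover much more but with less precision. `morphgloss` occupies
the middle ground: it assembles an explanation from the term's own
morphology.

The linguistic assumption is that medical vocabulary in English and
Spanish is built largely from Greek and Latin bound morphemes with
stable denotations. A *prefix* or *suffix* is any such unit with a
meaning apart from the word (e.g. *cardio-* "the heart"); a *root* is a
unit that can stand alone as a word (e.g. *vascular*). Semantic drift —
compositions whose meaning is not the sum of their parts — exists
(*antibodies* is not "against bodies") but is comparatively rare in
medical terminology. The package documents this failure mode rather
than attempting to detect it.

## The parsing procedure

`parse_term()` normalizes the input (lowercase, Unicode NFC), splits it
on any non-letter characters (separators are kept as glossless units so
the parse always reconstructs the input), and then runs, per letter
fragment and per recursion level:

1. **Affix identification.** Dictionary prefixes are compared against
   the fragment start and suffixes against the end, strictly longest
   form first with lexicographic tie-breaks. A match is only accepted
   if its removal leaves at least `min_root_length` characters. At most
   one prefix and one suffix are stripped per level, prefix first.
2. **Root lookup.** The remainder is searched through the backend
   cascade via `lookup_root()`: for each candidate variant, each
   backend is queried on the exact form and then on its stemmed form
   (backends carry a stemmed index of their vocabulary). The first hit
   supplies the root's definition and ends the branch.
3. **Recursion or residue.** If the lookup fails but an affix was
   stripped this level, the remainder re-enters step 1. If nothing was
   stripped and nothing was found, the remainder becomes a *residue*
   unit whose definition is its own surface — the reader at least sees
   which part could not be explained.

Each level strips at least one character, so recursion depth is bounded
by the term length; `max_depth` (default 25) is a guard against
dictionary pathology, not a tuning knob.

### Single-character root variants

Stripping an affix can clip a character off the true root. The
dictionary form *hyper-* leaves *glycemic* intact, but other matches are
less tidy, so lookup tries small edge variants of the remainder. Which
variants constitute "single character variations" is a genuinely open
design point; the package uses exactly three candidates, in order: the
bare remainder, the remainder with the adjacent boundary character of
the matched affix restored, and the remainder with one character
dropped at the matched edge. The restore rule is motivated by
prepend-style variants such as *aglycemic* for *glycemic*; the drop rule
is its symmetric counterpart. Both are toggleable through
`parser_config(variants = ...)` so the bare-remainder-only behaviour is
recoverable.

### Recursion after a successful lookup

A found root may itself still contain affixes. By default a successful
lookup ends the branch: the root's sourced definition is taken to be a
better explanation than a further decomposition. Setting
`parser_config(decompose_found_roots = TRUE)` inverts the preference —
the remainder is decomposed as long as affixes match, and the lookup
hit is used only when deeper decomposition yields pure residue.

### Stemming

Root lookup succeeds more often on stemmed forms: a lexicon may hold
*gastrointestine* but not *gastrointestinal*; both reduce to the common
stem *gastrointestin*. The stemming contract is a pure
`character -> character` function per language supplied via
`parser_config()`; the defaults are a Porter stemmer for English and a
Snowball-style stemmer for Spanish, both implemented in the package.
The Spanish stemmer removes attached pronouns, standard and verb
suffixes, and residual vowels, then strips acute accents; input
normalization itself never strips diacritics, since accented and
unaccented Spanish forms are different words and folding them would
create spurious matches.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_root_length` | 2 | characters | prevents short terms from being consumed entirely by their own affixes (e.g. *ic* is not parsed as the suffix *-ic* with an empty root) |
| `max_depth` | 25 | recursion levels | safety bound; any value at or above the longest expected term is equivalent |
| `variants` | restore + drop on | — | the three-candidate variant rule above |
| `threshold_rank` | 5000 | background rank | a term is difficult when its corpus frequency is strictly below the 5000th-ranked background term's frequency |
| palette | 8 colours | — | colour-coded rendering cycles a fixed palette; the alignment, not the specific colours, carries the information |

The difficulty predicate is *antitone* in `threshold_rank`: a deeper
rank means a rarer cutoff term, so the difficult set can only shrink.
Terms absent from the background list count as frequency 0 and are
always difficult.

## Frequency groups and balanced sampling

Difficult terms are split into frequency tertiles; only the lowest
(*low*) and uppermost (*high*) tertiles are sampled, middle-tertile
terms are discarded — the analyses the sampling serves contrast low
against high. Ties at tertile boundaries are ordered lexicographically
by term before slicing, so the assignment is deterministic; when all
frequencies are equal there is no tertile structure and everything is
assigned to *middle* with a warning.

`balanced_sample()` draws `n_per_class` terms per document class, split
exactly evenly between low and high, spread so per-document counts
within a class differ by at most one. The allocator is an
eligibility-aware greedy: it always extends the least-loaded document
that can still supply a needed group, preferring the group with the
larger remaining need. This handles realistic pools in which individual
documents lack one of the groups; a pool where even that fails (a
document with almost no eligible terms) raises an error naming the
deficient document rather than silently unbalancing the sample. The
greedy allocator is not a full bipartite matcher, so contrived pools
exist where a feasible assignment is declared infeasible; for study-like
pools (many eligible terms per document) this does not arise.

## Evaluation metrics

Per (term, source), the score is the mean across raters; a missing
score means "no explanation offered". Then per source: *quality* is the
mean over covered terms (1–4), *coverage* is covered/N, and
*usefulness* is the mean over all N terms with exact 0 for uncovered
terms — hence `usefulness = quality × coverage` as an arithmetic
identity, which the tests assert to 1e-12.

Best-choice agreement: each rater's *best set* for a term is the set of
sources achieving that rater's maximum score (ties allowed). The
conservative indicator requires identical best sets across raters, the
liberal one a non-empty intersection. Cronbach's alpha is computed with
raters as items over per-(term, source) scores; because the exact
pipeline from best sets to alpha is ambiguous, `agreement_alpha()`
offers both routes — alpha over raw scores (uncovered as 0) and alpha
over 0/1 best-set membership indicators — and reports the per-term
agreement rate alongside.

Cumulative cascade metrics combine sources into one system: coverage by
union, usefulness by per-term maximum (the higher-rated explanation
wins when two sources cover the same term). Both are non-decreasing
along any cascade by construction.

## Synthetic fixtures: what they emulate and what they do not

`generate_term_fixture()` emulates the *shape* of a stimulus study:
terms composed as `[prefix] + root + [suffix]` from the packaged affix
dictionaries (each affix present with probability 0.9), spread over 100
technical and 20 encyclopedic documents, 400 terms by default, with a
5000-entry background frequency list under which every composed term is
difficult and composed-term frequencies span the tertile range. A
companion lexicon resolves every generated root, and each record keeps
the true decomposition plus an `ambiguous` flag set when longest-first
matching against the dictionary would legitimately pick different
boundaries than the generator used (the flag is computed by an explicit
string scan, not by the parser). Boundary-recovery checks exclude
flagged records, since for them the generator's record is not the
unique correct parse.

`generate_rating_fixture()` draws per-source coverage Bernoulli(p) and
integer scores from a clipped normal around the configured mean,
recording the realized quality/coverage so metric recovery is checked
against the generator's own bookkeeping.
`ratings_from_marginals()` goes the other way: given printed
quality/coverage pairs it builds a two-rater table whose per-term means
are half-integer steps summing to the nearest realizable total, which
is how published marginals can be fed through `compute_metrics()`.

What passing these tests does **not** show about real data: synthetic
roots are phonotactically random, so real-term ambiguity (overlapping
affixes, drifted meanings, multi-affix stacks) is underrepresented;
backend coverage draws are independent across sources, while real
resources overlap systematically; and simulated Likert scores have no
rater idiosyncrasies. Quality judgments of real explanations are human
data and are outside what any fixture can validate.

## Numerical and degenerate-input choices

* All orderings that the algorithm depends on are total: affix
  candidates by (length desc, form), nearest-neighbour ties
  lexicographic, tertile ties lexicographic. Identical inputs and seeds
  give identical outputs everywhere.
* Embedding similarity is cosine; zero-norm vectors are pushed to
  -Inf similarity rather than producing NaN winners. A query absent
  from the vocabulary is "no coverage" (empty result), not an error.
  Case/diacritic variants of the query are excluded from the neighbour
  pool — they are the same word, not a synonym.
* Cronbach's alpha on a zero-variance matrix is undefined and raises an
  error; negative alpha is returned as is.
* Empty inputs error early with the offending record or line named:
  empty affix files, records lacking form or position, duplicate
  (form, position) keys, scores outside 1–4, duplicate
  (term, source, rater) rows.
* The seeded RNG is always used through a local scope that restores the
  caller's RNG state, so library calls never perturb user simulations.

## Problem sizes

The shipped test-and-verification workload uses: 500+ fuzzed parse
inputs (length ≤ 40), 500 synthetic compositions for boundary recovery,
embedding tables up to 1,000 words against a brute-force cosine oracle,
rating studies of 120–400 terms, and n = 1000 independent-rater alpha
simulations. These sizes make every check a matter of seconds while
keeping the estimates (recovery rates, alpha under independence) stable
across seeds.

## Known limitations

* Affix matching is purely orthographic; the system cannot tell whether
  matched characters are a true morpheme, and a correct morphological
  parse can still be a wrong explanation under semantic drift.
* Explanations can be partial: a parse may gloss *-al* in *distal* while
  leaving *dist* as residue, which helps a reader little.
* Multiword phrases are not handled; tokenization is single-word by
  design.
* The packaged dictionaries and lexicons are small fixtures sufficient
  for the worked examples and tests; production use expects real affix
  dictionaries and licensed lexicon resources in the same TSV formats.
* The embedding source is standalone: it is not consulted inside the
  parser cascade, mirroring the evaluation design this package
  implements (using embeddings for per-root synonym lookup is a natural
  extension, deliberately not included).
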