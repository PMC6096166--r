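Package: morphgloss
Title: Morphological Decomposition and Plain-Language Explanation of
    Medical Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates plain-language explanations for difficult medical
    terms in English and Spanish by decomposing them into morphological
    units.  Terms are parsed recursively against specialized Greek/Latin
    affix dictionaries (longest match first), remaining roots are looked
    up in cascaded lexicon backends (consumer-health and general-purpose
    dictionaries, plus a word-embedding nearest-neighbour synonym
    source), and the sourced definitions are assembled into an aligned,
    optionally colour-coded gloss.  Also provides the supporting study
    machinery: difficult-term identification by corpus-frequency rank
    (term familiarity), frequency-tertile grouping and balanced stimulus
    sampling, and evaluation metrics over expert Likert ratings
    (quality, coverage, usefulness, best-choice agreement, Cronbach's
    alpha, and cumulative cascade metrics), together with seeded
    synthetic fixture generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
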