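test_that("edge matching takes the longest anchoring affix", {
  d <- tiny_dict()
  expect_equal(match_edge_affix("antihero", d, "prefix")$form, "anti")
  expect_equal(match_edge_affix("hyperglycemic", builtin_affix_dictionary("en"),
                                "prefix")$form, "hyper")
  # removal must leave a root of the minimum length
  only_ic <- affix_dictionary(data.frame(form = "-ic", position = "suffix",
                                         definition = "pertaining to"), "en")
  expect_null(match_edge_affix("ic", only_ic, "suffix", min_root_length = 2))
  expect_null(match_edge_affix("bic", only_ic, "suffix", min_root_length = 2))
  expect_equal(match_edge_affix("basic", only_ic, "suffix")$form, "ic")
})

test_that("root variants enumerate bare, restored and dropped forms in order", {
  expect_equal(root_variants("glycemic", "start", "r"),
               c("glycemic", "rglycemic", "lycemic"))
  expect_equal(root_variants("vascul", "end", "a"),
               c("vascul", "vascula", "vascu"))
  # one-character root: drop variant would be empty, so it is excluded
  expect_equal(root_variants("x", "end", "s"), c("x", "xs"))
  # duplicate-free even when rules collide
  expect_equal(root_variants("aa", "start", "a"), c("aa", "aaa", "a"))
  # rules are toggleable
  expect_equal(root_variants("abc", "start", "z",
                             rules = c(restore = FALSE, drop = FALSE)), "abc")
})

test_that("root lookup cascades over variants, backends and stems", {
  wn <- builtin_backends("en")$wordnet
  hit <- lookup_root("vascular", list(wn))
  expect_equal(hit$text, "consisting of a vessel or vessels")
  expect_equal(attr(hit, "variant"), "vascular")

  # stemmed fallback: lexicon holds the noun, query is the adjective
  b <- tiny_backend("gastrointestine", texts = "the stomach and intestine",
                    stemmer = porter_stem)
  hit <- lookup_root("gastrointestinal", list(b))
  expect_equal(hit$text, "the stomach and intestine")

  # cascade order decides between competing backends
  b1 <- tiny_backend("vascular", texts = "first", name = "one")
  b2 <- tiny_backend("vascular", texts = "second", name = "two")
  expect_equal(lookup_root("vascular", list(b1, b2))$source, "one")
  expect_equal(lookup_root("vascular", list(b2, b1))$source, "two")

  expect_null(lookup_root("qqqq", list(wn)))
  expect_null(lookup_root("qqqq", list()))
})

test_that("worked parses recover the expected unit decompositions", {
  d <- builtin_affix_dictionary("en")
  b <- builtin_backends("en")

  p <- parse_term("hyperglycemic", d, b)
  expect_equal(p$units$surface, c("hyper", "glyc", "em", "ic"))
  expect_equal(p$units$kind, c("prefix", "prefix", "residue", "suffix"))
  expect_equal(p$units$definition,
               c("denotes something as extreme or beyond normal",
                 "sugar", "em", "pertaining to"))
  expect_equal(p$units$source[3], "unresolved")

  p <- parse_term("cardiovascular", d, b)
  expect_equal(p$units$surface, c("cardio", "vascular"))
  expect_equal(p$units$kind, c("prefix", "root"))
  expect_equal(p$units$definition,
               c("the heart", "consisting of a vessel or vessels"))
  expect_equal(p$units$source[2], "wordnet")

  # unknown term with no affixes and no backend entry: identity residue
  p <- parse_term("zumba", d, b)
  expect_equal(p$units$surface, "zumba")
  expect_equal(p$units$kind, "residue")
  expect_equal(p$units$definition, "zumba")

  expect_error(parse_term("", d, b), "empty")
})

test_that("longest-first precedence picks anti over a in antihero", {
  d <- tiny_dict()
  p <- parse_term("antihero", d)
  expect_true("anti" %in% p$units$surface)
  expect_false("a" %in% p$units$surface[p$units$kind == "prefix"])
})

test_that("hyphens and other non-word characters split the term", {
  d <- builtin_affix_dictionary("en")
  p <- parse_term("anti-hero", d)
  # the hyphen is kept as a glossless separator unit and each letter
  # fragment is parsed on its own
  expect_true("separator" %in% p$units$kind)
  expect_equal(p$units$surface[p$units$kind == "separator"], "-")
  expect_equal(paste(p$units$surface, collapse = ""), "anti-hero")

  p2 <- parse_term("Beta2-agonist", d)
  expect_equal(paste(p2$units$surface, collapse = ""), "beta2-agonist")
})

test_that("parsing is deterministic and reconstructs fuzzed inputs", {
  d <- builtin_affix_dictionary("en")
  b <- builtin_backends("en")
  cfg <- parser_config("en")
  terms <- random_terms(150, max_len = 40, with_punct = TRUE, seed = 99)
  terms <- terms[nzchar(mg_normalize(terms))]
  for (tm in terms) {
    p <- parse_term(tm, d, b, cfg)
    expect_equal(paste(p$units$surface, collapse = ""), mg_normalize(tm))
    expect_lte(p$depth, nchar(mg_normalize(tm)))
  }
  tm <- terms[1]
  expect_identical(parse_term(tm, d, b, cfg), parse_term(tm, d, b, cfg))
})

test_that("parser recovers generator ground truth on synthetic compositions", {
  spec <- fixture_spec(seed = 5, n_terms = 120)
  fix <- generate_term_fixture(spec)
  d <- builtin_affix_dictionary("en")
  backends <- list(fix$root_backend)
  clean <- fix$terms[!fix$terms$ambiguous, ]
  expect_gt(nrow(clean), 50)
  hits <- 0
  for (i in seq_len(nrow(clean))) {
    rec <- clean[i, ]
    p <- parse_term(rec$term, d, backends)
    expected <- c(if (nzchar(rec$prefix)) rec$prefix, rec$root,
                  if (nzchar(rec$suffix)) rec$suffix)
    if (identical(p$units$surface, expected)) hits <- hits + 1
  }
  expect_equal(hits, nrow(clean))
})

test_that("a found root can optionally be decomposed further", {
  d <- builtin_affix_dictionary("en")
  # backend whose stemmed index resolves the inner remainder directly
  b <- list(tiny_backend("glycemic", texts = "relating to blood sugar",
                         stemmer = porter_stem))
  # default: the lookup hit ends the branch
  p <- parse_term("hyperglycemic", d, b)
  expect_equal(p$units$surface, c("hyper", "glycem", "ic"))
  expect_equal(p$units$kind, c("prefix", "root", "suffix"))
  # flag on: the remainder is split further while affixes still match
  cfg <- parser_config("en", decompose_found_roots = TRUE)
  p2 <- parse_term("hyperglycemic", d, b, cfg)
  expect_equal(p2$units$surface, c("hyper", "glyc", "em", "ic"))
})
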