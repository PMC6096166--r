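#' Packaged resources
#'
#' Small English and Spanish affix dictionaries (every commonly cited
#' Greek/Latin medical affix plus enough others for realistic parsing)
#' and synthetic stand-ins for the lexicon backends: a consumer-health
#' style lexicon (`"chv"`), a general lexical database style lexicon
#' (`"wordnet"`), and a tiny hand-set embedding table (file name marks
#' it as synthetic).  These ship with the package so the worked
#' examples run out of the box; they are fixtures, not the licensed
#' resources they emulate.
#'
#' @param language `"en"` or `"es"`.
#' @return [builtin_affix_dictionary()]: an [affix_dictionary()].
#'   [builtin_backends()]: named list of backends in cascade order
#'   (consumer-health lexicon first, then the general lexicon).
#'   [builtin_embedding()]: an [embedding_table()] (English only).
#' @export
builtin_affix_dictionary <- function(language = c("en", "es")) {
  language <- match.arg(language)
  path <- system.file("extdata", paste0("affixes_", language, ".tsv"),
                      package = "morphgloss", mustWork = TRUE)
  load_affix_dictionary(path, language)
}

#' @rdname builtin_affix_dictionary
#' @param stemmer stemming function for the backends' stemmed indexes;
#'   `NULL` selects the language default.
#' @export
builtin_backends <- function(language = c("en", "es"), stemmer = NULL) {
  language <- match.arg(language)
  if (is.null(stemmer)) stemmer <- default_stemmer(language)
  wn <- load_lexicon(
    system.file("extdata", paste0("lexicon_wordnet_", language, ".tsv"),
                package = "morphgloss", mustWork = TRUE),
    name = "wordnet", stemmer = stemmer)
  if (language == "en") {
    chv <- load_lexicon(
      system.file("extdata", "lexicon_chv_en.tsv", package = "morphgloss",
                  mustWork = TRUE),
      name = "chv", stemmer = stemmer)
    list(chv = chv, wordnet = wn)
  } else {
    list(wordnet = wn)
  }
}

#' @rdname builtin_affix_dictionary
#' @export
builtin_embedding <- function() {
  read_word2vec(system.file("extdata", "embeddings_en_synthetic.txt",
                            package = "morphgloss", mustWork = TRUE),
                name = "embedding")
}

#' Fixture specification
#'
#' One seeded description of a complete synthetic study: how many
#' stimulus terms, how they are spread over documents of the two
#' classes, the background-frequency threshold, the probability that a
#' composed term carries a prefix/suffix, and the per-source coverage
#' probabilities and Likert score means used for rating tables.  An
#' identical spec always regenerates identical fixtures.
#'
#' Defaults mirror the stimulus design the package's evaluation
#' machinery is built around: 400 terms, 200 per document class, drawn
#' from 100 technical and 20 encyclopedic documents, difficulty cutoff
#' at the 5000th background rank.
#'
#' @param seed integer seed; all fixture randomness flows from it.
#' @param language `"en"` or `"es"`.
#' @param n_terms number of stimulus terms.
#' @param n_docs named integer vector: documents per class.
#' @param threshold_rank background difficulty rank cutoff.
#' @param p_prefix,p_suffix probability that a composed term carries a
#'   prefix / suffix.
#' @param sources data frame `source`, `coverage_prob`, `mean_score`
#'   for rating-table generation.
#' @param n_raters number of simulated raters.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         language = c("en", "es"),
                         n_terms = 400L,
                         n_docs = c(technical = 100L, encyclopedic = 20L),
                         threshold_rank = 5000L,
                         p_prefix = 0.9,
                         p_suffix = 0.9,
                         sources = data.frame(
                           source = c("chv", "wordnet_synonym",
                                      "wordnet_summary", "morphgloss",
                                      "embedding"),
                           coverage_prob = c(0.06, 0.53, 0.53, 0.805, 0.838),
                           mean_score = c(2.81, 2.09, 3.32, 1.64, 1.64),
                           stringsAsFactors = FALSE),
                         n_raters = 2L) {
  language <- match.arg(language)
  mg_assert(all(c("technical", "encyclopedic") %in% names(n_docs)),
            "`n_docs` needs entries 'technical' and 'encyclopedic'")
  mg_assert(all(sources$coverage_prob >= 0 & sources$coverage_prob <= 1),
            "coverage probabilities must lie in [0, 1]")
  mg_assert(all(sources$mean_score >= 1 & sources$mean_score <= 4),
            "mean scores must lie on the 1-4 scale")
  structure(list(seed = as.integer(seed), language = language,
                 n_terms = as.integer(n_terms), n_docs = n_docs,
                 threshold_rank = as.integer(threshold_rank),
                 p_prefix = p_prefix, p_suffix = p_suffix,
                 sources = sources, n_raters = as.integer(n_raters)),
            class = "fixture_spec")
}

# pronounceable random root: alternating consonant/vowel runs
random_roots <- function(n, min_len = 5L, max_len = 8L) {
  cons <- strsplit("bcdfgklmnprstvz", "")[[1]]
  vows <- strsplit("aeiou", "")[[1]]
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    ch <- character(len)
    start_c <- runif(1) < 0.7
    for (j in seq_len(len)) {
      pool <- if ((j %% 2 == 1) == start_c) cons else vows
      ch[j] <- sample(pool, 1)
    }
    paste(ch, collapse = "")
  }, character(1))
}

# longest anchoring affix computed by explicit loop (generator-side
# check, deliberately not reusing the parser's matcher)
brute_longest_edge <- function(term, forms, edge, min_root = 2L) {
  ok <- if (edge == "start") startsWith(term, forms) else endsWith(term, forms)
  ok <- ok & (nchar(term) - nchar(forms)) >= min_root
  if (!any(ok)) return("")
  f <- forms[ok]
  f[order(-nchar(f), f, method = "radix")][1]
}

#' Generate a synthetic term corpus with known decompositions
#'
#' Composes stimulus terms as `[prefix] + root + [suffix]` from the
#' affix dictionary and a pool of random roots, spreads them over
#' documents of the two classes, builds a background frequency list in
#' which every composed term falls below the difficulty threshold (with
#' frequencies spanning the tertile range), and records each term's
#' true decomposition.  A companion lexicon backend containing every
#' root is returned so a parser can resolve them.
#'
#' Each record carries an `ambiguous` flag, set when longest-first
#' matching against the dictionary would pick different unit boundaries
#' than the generator used (e.g. the composed surface happens to start
#' with a longer dictionary prefix).  Boundary-recovery checks exclude
#' flagged records: for those, the generator's record is not the unique
#' correct parse.
#'
#' @param spec a [fixture_spec()].
#' @param dict affix dictionary to compose from; default the packaged
#'   dictionary for `spec$language`.
#' @param dir optional directory; when given, the corpus, frequency
#'   list, truth table and root lexicon are also written there as
#'   TSV files.
#' @return list with `terms` (truth table: term, prefix, root, suffix,
#'   frequency, source_doc, doc_class, ambiguous), `documents`,
#'   `frequency` (background list), and `root_backend`.
#' @export
generate_term_fixture <- function(spec, dict = NULL, dir = NULL) {
  mg_assert(inherits(spec, "fixture_spec"), "`spec` is not a fixture_spec")
  if (is.null(dict)) dict <- builtin_affix_dictionary(spec$language)
  prefixes <- candidate_affixes(dict, "prefix")
  suffixes <- candidate_affixes(dict, "suffix")
  mg_assert(nrow(prefixes) > 0 && nrow(suffixes) > 0,
            "affix pool is empty; cannot compose terms")

  with_seed(spec$seed, {
    n <- spec$n_terms
    # background list: threshold_rank common fillers with distinct
    # descending counts, so the threshold count is unambiguous
    n_bg <- spec$threshold_rank
    bg_terms <- paste0("common", formatC(seq_len(n_bg), width = 6, flag = "0"))
    bg_counts <- seq(n_bg * 10, by = 10, length.out = n_bg)[n_bg:1]
    threshold_count <- 10  # count of the threshold-ranked filler

    if (n == 0) {
      truth <- data.frame(term = character(), prefix = character(),
                          root = character(), suffix = character(),
                          frequency = numeric(), source_doc = character(),
                          doc_class = character(), ambiguous = logical(),
                          stringsAsFactors = FALSE)
      documents <- data.frame(doc_id = character(), doc_class = character(),
                              text = character(), stringsAsFactors = FALSE)
    } else {
      roots <- unique(random_roots(3L * n))
      roots <- setdiff(roots, c(bg_terms, prefixes$form, suffixes$form))
      mg_assert(length(roots) >= n, "root pool too small; increase n_terms margin")
      roots <- roots[seq_len(n)]
      pre <- ifelse(runif(n) < spec$p_prefix,
                    sample(prefixes$form, n, replace = TRUE), "")
      suf <- ifelse(runif(n) < spec$p_suffix,
                    sample(suffixes$form, n, replace = TRUE), "")
      term <- paste0(pre, roots, suf)

      # document assignment: even split over classes, round-robin over
      # each class's documents
      cls <- rep(c("technical", "encyclopedic"), each = ceiling(n / 2))[seq_len(n)]
      doc <- character(n)
      for (cl in unique(cls)) {
        ids <- paste0(substr(cl, 1, 4), "_", sprintf("%03d", seq_len(spec$n_docs[[cl]])))
        sel <- which(cls == cl)
        doc[sel] <- rep(ids, length.out = length(sel))
      }

      # all composed terms are difficult: frequencies span [0, threshold)
      freq <- sample(0:(threshold_count - 1), n, replace = TRUE)

      amb <- vapply(seq_len(n), function(i) {
        bp <- brute_longest_edge(term[i], prefixes$form, "start")
        if (bp != pre[i]) return(TRUE)
        rem <- substr(term[i], nchar(pre[i]) + 1L, nchar(term[i]))
        bs <- brute_longest_edge(rem, suffixes$form, "end")
        if (bs != suf[i]) return(TRUE)
        term[i] %in% roots  # a whole term colliding with a root
      }, logical(1))

      dup <- duplicated(term)
      truth <- data.frame(term = term, prefix = pre, root = roots,
                          suffix = suf, frequency = freq, source_doc = doc,
                          doc_class = cls, ambiguous = amb | dup,
                          stringsAsFactors = FALSE)
      texts <- vapply(split(truth$term, truth$source_doc), paste,
                      character(1), collapse = " ")
      documents <- data.frame(doc_id = names(texts),
                              doc_class = truth$doc_class[
                                match(names(texts), truth$source_doc)],
                              text = unname(texts), stringsAsFactors = FALSE)
      documents <- documents[order(documents$doc_id), , drop = FALSE]
      rownames(documents) <- NULL
    }

    frequency <- rbind(
      data.frame(term = bg_terms, count = bg_counts, stringsAsFactors = FALSE),
      if (nrow(truth) > 0) {
        keep <- truth$frequency > 0 & !duplicated(truth$term)
        data.frame(term = truth$term[keep], count = truth$frequency[keep],
                   stringsAsFactors = FALSE)
      })
    root_backend <- lexicon_backend(
      if (nrow(truth) > 0) {
        data.frame(term = truth$root,
                   style = "summary",
                   text = paste("synthetic definition of", truth$root),
                   stringsAsFactors = FALSE)[!duplicated(truth$root), ]
      } else {
        data.frame(term = "placeholder", style = "summary",
                   text = "placeholder entry", stringsAsFactors = FALSE)
      },
      name = "root_lexicon", stemmer = default_stemmer(spec$language))

    out <- list(terms = truth, documents = documents, frequency = frequency,
                root_backend = root_backend)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write.table(truth, file.path(dir, "terms_truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
      write.table(documents, file.path(dir, "documents.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
      write.table(frequency, file.path(dir, "frequency.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
      write_lexicon(root_backend, file.path(dir, "root_lexicon.tsv"))
    }
    out
  })
}

#' Generate a synthetic rating table with known metrics
#'
#' For every source in the spec, covers each term independently with
#' the configured probability and draws integer 1-4 scores around the
#' configured mean for each rater.  The realized per-source quality and
#' coverage are recorded from the draws themselves, so metric recovery
#' is checkable against the generator's own bookkeeping.  Uncovered
#' (term, source) pairs are emitted with `NA` scores for every rater --
#' the source offered no explanation there.
#'
#' @param spec a [fixture_spec()].
#' @param terms character vector of term ids; default `t0001`...
#' @return list with `ratings` (term, source, rater, score) and
#'   `realized` (source, quality, coverage, usefulness as realized).
#' @export
generate_rating_fixture <- function(spec, terms = NULL) {
  mg_assert(inherits(spec, "fixture_spec"), "`spec` is not a fixture_spec")
  if (is.null(terms)) {
    terms <- paste0("t", formatC(seq_len(spec$n_terms), width = 4, flag = "0"))
  }
  n <- length(terms)
  mg_assert(n >= 1, "need at least one term")
  with_seed(spec$seed + 1L, {
    rows <- list()
    realized <- list()
    for (k in seq_len(nrow(spec$sources))) {
      src <- spec$sources$source[k]
      p <- spec$sources$coverage_prob[k]
      mu <- spec$sources$mean_score[k]
      covered <- runif(n) < p
      score_mat <- matrix(NA_real_, nrow = spec$n_raters, ncol = n)
      if (any(covered)) {
        idx <- which(covered)
        for (r in seq_len(spec$n_raters)) {
          raw <- round(stats::rnorm(length(idx), mean = mu, sd = 0.8))
          score_mat[r, idx] <- pmin(4, pmax(1, raw))
        }
      }
      for (r in seq_len(spec$n_raters)) {
        rows[[length(rows) + 1L]] <- data.frame(
          term = terms, source = src, rater = paste0("rater", r),
          score = score_mat[r, ], stringsAsFactors = FALSE)
      }
      per_term <- colMeans(score_mat)
      q <- if (any(covered)) mean(per_term[covered]) else NA_real_
      realized[[k]] <- data.frame(
        source = src, quality = q, coverage = mean(covered),
        usefulness = sum(per_term[covered]) / n, stringsAsFactors = FALSE)
    }
    list(ratings = do.call(rbind, rows),
         realized = do.call(rbind, realized))
  })
}

#' Build a rating table realizing given quality/coverage marginals
#'
#' Constructs the smallest-structure rating table (two raters by
#' default) whose realized per-source quality and coverage round to the
#' given values: per-term mean scores are half-integer steps on the 1-4
#' scale, chosen so their total is the half-integer closest to
#' `quality x covered`.  Useful for reproducing the arithmetic identity
#' usefulness = quality x coverage from published marginals.
#'
#' @param marginals data frame `source`, `quality` (1-4), `covered`
#'   (integer count of covered terms).
#' @param n_terms total number of study terms (>= max covered).
#' @param n_raters number of raters to spread scores over (default 2).
#' @return rating data frame `term`, `source`, `rater`, `score`.
#' @export
ratings_from_marginals <- function(marginals, n_terms, n_raters = 2L) {
  mg_assert(is.data.frame(marginals) &&
              all(c("source", "quality", "covered") %in% names(marginals)),
            "`marginals` needs columns source, quality, covered")
  mg_assert(all(marginals$covered <= n_terms),
            "covered counts exceed n_terms")
  mg_assert(all(marginals$quality >= 1 & marginals$quality <= 4),
            "quality must lie on the 1-4 scale")
  mg_assert(n_raters == 2L,
            "only 2 raters can realize half-integer per-term means exactly")
  terms <- paste0("t", formatC(seq_len(n_terms), width = 5, flag = "0"))
  rows <- list()
  for (k in seq_len(nrow(marginals))) {
    src <- marginals$source[k]
    cov <- marginals$covered[k]
    if (cov == 0) {
      score_half <- integer(0)
    } else {
      total_half <- round(marginals$quality[k] * cov * 2)
      base <- total_half %/% cov
      extra <- total_half %% cov
      score_half <- rep(base, cov)
      if (extra > 0) score_half[seq_len(extra)] <- base + 1L
      mg_assert(all(score_half >= 2 & score_half <= 8),
                "marginals for '", src, "' cannot be realized on the 1-4 scale")
    }
    per_term <- c(score_half / 2, rep(NA_real_, n_terms - cov))
    # spread half-steps over two raters: floor and ceiling of the mean
    r1 <- ifelse(is.na(per_term), NA_real_, floor(per_term))
    r2 <- ifelse(is.na(per_term), NA_real_, ceiling(per_term))
    raters <- list(r1, r2)
    for (r in seq_along(raters)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = terms, source = src, rater = paste0("rater", r),
        score = raters[[r]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Random embedding table fixture
#'
#' @param n_words vocabulary size.
#' @param dim vector dimensionality.
#' @param seed integer seed.
#' @return an [embedding_table()] with words `w0001`...
#' @export
fixture_embedding <- function(n_words, dim = 8L, seed = 1L) {
  with_seed(seed, {
    m <- matrix(stats::rnorm(n_words * dim), nrow = n_words)
    rownames(m) <- paste0("w", formatC(seq_len(n_words), width = 4, flag = "0"))
    embedding_table(m, name = "embedding")
  })
}
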