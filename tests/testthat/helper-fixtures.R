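# shared in-code fixtures; everything is built at test time

tiny_dict <- function() {
  affix_dictionary(data.frame(
    form = c("anti-", "a-", "hyper-", "glyc-", "cardio-",
             "-ic", "-al", "-er", "-s"),
    position = c(rep("prefix", 5), rep("suffix", 4)),
    definition = c("against", "not, without", "extreme", "sugar", "the heart",
                   "pertaining to", "pertaining to", "one who", "plural"),
    stringsAsFactors = FALSE), language = "en")
}

tiny_backend <- function(terms, texts = paste("def of", terms),
                         styles = "summary", name = "lex", stemmer = NULL) {
  lexicon_backend(data.frame(term = terms, style = styles, text = texts,
                             stringsAsFactors = FALSE),
                  name = name, stemmer = stemmer)
}

# brute-force cosine nearest neighbour, the independent oracle for the
# embedding backend
oracle_nearest <- function(tab, query, exclude = character()) {
  v <- tab$vectors
  fold <- function(x) stringi::stri_trans_general(tolower(x), "Latin-ASCII")
  cand <- setdiff(rownames(v), c(query, exclude))
  cand <- cand[fold(cand) != fold(query)]
  if (length(cand) == 0) return(NULL)
  qv <- v[query, ]
  sims <- vapply(cand, function(w) {
    sum(v[w, ] * qv) / sqrt(sum(v[w, ]^2) * sum(qv^2))
  }, numeric(1))
  best <- max(sims)
  sort(cand[sims == best])[1]
}

# random letter strings (with optional punctuation) for fuzzing
random_terms <- function(n, max_len = 40, with_punct = FALSE, seed = 42) {
  set.seed(seed)
  pool <- c(letters, if (with_punct) c("-", "-", "1", " ", "'"))
  vapply(seq_len(n), function(i) {
    len <- sample.int(max_len, 1)
    paste(sample(pool, len, replace = TRUE), collapse = "")
  }, character(1))
}

# small deterministic rating table: 2 raters, controllable per-source
# coverage and scores
make_ratings <- function(scores_by_source, terms, raters = c("r1", "r2")) {
  rows <- list()
  for (src in names(scores_by_source)) {
    sc <- scores_by_source[[src]]  # per-term mean, NA = uncovered
    for (i in seq_along(raters)) {
      s <- if (i == 1) floor(sc) else ceiling(sc)
      rows[[length(rows) + 1]] <- data.frame(
        term = terms, source = src, rater = raters[i], score = s,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
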