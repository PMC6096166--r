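#' Lexicon backends
#'
#' An explanation source behind a uniform lookup contract.  Two flavours
#' exist: dictionary-backed lexicons (a consumer-health vocabulary or a
#' general-purpose lexical database, held as term/style/text records)
#' and an embedding table whose "explanation" for a term is its nearest
#' neighbour in vector space (see [nearest_neighbor_synonym()]).
#'
#' Lexicon entries carry an explanation style: `"synonym"` for
#' single-word or short-phrase replacements (lexical simplification),
#' `"summary"` for free-text definitions (semantic simplification).
#' Multi-sense terms are ordered by `sense_rank`; sense 1 is returned
#' first on lookup.
#'
#' @param entries data frame with columns `term`, `style`
#'   (`"synonym"`/`"summary"`), `text` and optionally `sense_rank`
#'   (defaults to within-term record order).
#' @param name backend name used in provenance fields of explanations.
#' @param stemmer optional stemming function; when supplied, a stemmed
#'   index is built so that [lookup()] with `stemmed = TRUE` can match a
#'   query stem against stems of the stored terms.
#' @return an object of class `lexicon_backend`.
#' @export
lexicon_backend <- function(entries, name, stemmer = NULL) {
  mg_assert(is.data.frame(entries), "`entries` must be a data frame")
  needed <- c("term", "style", "text")
  missing_cols <- setdiff(needed, names(entries))
  mg_assert(length(missing_cols) == 0,
            "lexicon entries lack column(s): ", paste(missing_cols, collapse = ", "))
  mg_assert(is.character(name) && length(name) == 1 && nzchar(name),
            "backend `name` must be a non-empty string")
  entries$term <- mg_normalize(trimws(entries$term))
  entries$style <- tolower(trimws(entries$style))
  mg_assert(all(entries$style %in% c("synonym", "summary")),
            "entry style must be 'synonym' or 'summary'")
  mg_assert(all(nzchar(entries$text)), "entry text must be non-empty")
  if (is.null(entries$sense_rank)) {
    entries$sense_rank <- stats::ave(seq_len(nrow(entries)), entries$term,
                                     FUN = seq_along)
  }
  entries$sense_rank <- as.integer(entries$sense_rank)
  ord <- order(entries$term, entries$sense_rank, method = "radix")
  entries <- entries[ord, c("term", "style", "text", "sense_rank"), drop = FALSE]
  rownames(entries) <- NULL
  stems <- if (!is.null(stemmer)) stemmer(entries$term) else NULL
  structure(list(name = name, entries = entries, stems = stems,
                 stemmer = stemmer),
            class = "lexicon_backend")
}

#' Read a lexicon backend from a TSV file
#'
#' Format: UTF-8 TSV with header `term style text sense_rank`.
#'
#' @inheritParams lexicon_backend
#' @param path path to the TSV file.
#' @return a [lexicon_backend()].
#' @export
load_lexicon <- function(path, name, stemmer = NULL) {
  mg_assert(file.exists(path), "lexicon file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  lexicon_backend(raw, name = name, stemmer = stemmer)
}

#' @rdname load_lexicon
#' @param backend a [lexicon_backend()].
#' @export
write_lexicon <- function(backend, path) {
  mg_assert(inherits(backend, "lexicon_backend"), "not a lexicon_backend")
  write.table(backend$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up a term in a backend
#'
#' Exact match on the normalized term.  Returns zero or more entries as
#' a data frame with columns `term`, `text`, `style`, `source`, ordered
#' primary sense first.  With `stemmed = TRUE` (lexicon backends built
#' with a stemmer only), the stem of `term` is matched against stems of
#' the stored vocabulary, so an inflected query can hit a base form.
#'
#' @param backend a backend object.
#' @param term the query term.
#' @param ... passed to methods.
#' @return data frame of entries; zero rows when the term is not
#'   covered.
#' @export
lookup <- function(backend, term, ...) UseMethod("lookup")

#' @rdname lookup
#' @param stemmed match by stem rather than surface form.
#' @export
lookup.lexicon_backend <- function(backend, term, stemmed = FALSE, ...) {
  mg_assert(length(term) == 1 && is.character(term), "`term` must be one string")
  q <- mg_normalize(term)
  if (isTRUE(stemmed)) {
    mg_assert(!is.null(backend$stems),
              "backend '", backend$name, "' was built without a stemmer")
    hit <- backend$stems == backend$stemmer(q)
  } else {
    hit <- backend$entries$term == q
  }
  rows <- backend$entries[hit, , drop = FALSE]
  if (nrow(rows) == 0) return(empty_entries())
  rows <- rows[order(rows$sense_rank, rows$term, method = "radix"), , drop = FALSE]
  data.frame(term = rows$term, text = rows$text, style = rows$style,
             source = backend$name, stringsAsFactors = FALSE)
}

empty_entries <- function() {
  data.frame(term = character(), text = character(), style = character(),
             source = character(), stringsAsFactors = FALSE)
}

#' @export
print.lexicon_backend <- function(x, ...) {
  cat(sprintf("<lexicon_backend '%s': %d entries, %d terms%s>\n",
              x$name, nrow(x$entries), length(unique(x$entries$term)),
              if (is.null(x$stems)) "" else ", stemmed index"))
  invisible(x)
}

# ---- embedding backend --------------------------------------------------

#' Word-embedding table
#'
#' Dense word vectors in the usual text interchange format: a header
#' line `n_words dim`, then one word per line followed by its vector
#' components.  Lookup is exact match on the normalized form; the
#' explanation a table offers for a term is its nearest neighbour by
#' cosine similarity.
#'
#' @param vectors numeric matrix, one row per word, rownames = words.
#' @param name backend name (default `"embedding"`).
#' @return an object of class `embedding_table`.
#' @export
embedding_table <- function(vectors, name = "embedding") {
  mg_assert(is.matrix(vectors) && is.numeric(vectors),
            "`vectors` must be a numeric matrix")
  mg_assert(!is.null(rownames(vectors)), "vector matrix must have word rownames")
  rownames(vectors) <- mg_normalize(rownames(vectors))
  mg_assert(!anyDuplicated(rownames(vectors)),
            "duplicate words in embedding vocabulary after normalization")
  structure(list(name = name, vectors = vectors), class = "embedding_table")
}

#' @rdname embedding_table
#' @param path path to a word2vec-style text file.
#' @export
read_word2vec <- function(path, name = "embedding") {
  mg_assert(file.exists(path), "embedding file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  mg_assert(length(lines) >= 1, "embedding file is empty: ", path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  mg_assert(length(hdr) == 2,
            "embedding file must start with a 'n_words dim' header line")
  n <- as.integer(hdr[1]); dim <- as.integer(hdr[2])
  mg_assert(length(lines) == n + 1,
            "embedding header declares ", n, " words but file has ",
            length(lines) - 1)
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  words <- vapply(parts, `[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  rownames(vecs) <- words
  embedding_table(vecs, name = name)
}

#' @rdname embedding_table
#' @param table an `embedding_table`.
#' @export
write_word2vec <- function(table, path) {
  mg_assert(inherits(table, "embedding_table"), "not an embedding_table")
  v <- table$vectors
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(v), ncol(v)), con)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], format(v[i, ], trim = TRUE, scientific = FALSE)),
          collapse = " ")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Nearest-neighbour synonym from an embedding table
#'
#' Returns the vocabulary word with the highest cosine similarity to the
#' query, excluding the query itself, anything in `exclude`, and words
#' that differ from the query only by case or diacritics (those are the
#' same word, not a synonym).  Ties are broken lexicographically so the
#' result is deterministic.  A query absent from the vocabulary yields
#' zero rows -- that source simply does not cover the term.
#'
#' @param table an [embedding_table()].
#' @param term query term.
#' @param exclude character vector of words never to return.
#' @return data frame with columns `term`, `text`, `style`, `source`
#'   (zero or one row; style is `"synonym"`).
#' @export
nearest_neighbor_synonym <- function(table, term, exclude = character()) {
  mg_assert(inherits(table, "embedding_table"), "not an embedding_table")
  q <- mg_normalize(term)
  v <- table$vectors
  if (!q %in% rownames(v)) return(empty_entries())
  fold <- function(x) stringi::stri_trans_general(mg_normalize(x), "Latin-ASCII")
  cand <- setdiff(rownames(v), c(q, mg_normalize(exclude)))
  cand <- cand[fold(cand) != fold(q)]
  if (length(cand) == 0) return(empty_entries())
  qv <- v[q, ]
  m <- v[cand, , drop = FALSE]
  sims <- as.vector(m %*% qv) / (sqrt(rowSums(m^2)) * sqrt(sum(qv^2)))
  sims[!is.finite(sims)] <- -Inf
  best <- cand[order(-sims, cand, method = "radix")][1]
  data.frame(term = q, text = best, style = "synonym", source = table$name,
             stringsAsFactors = FALSE)
}

#' @rdname lookup
#' @export
lookup.embedding_table <- function(backend, term, ...) {
  nearest_neighbor_synonym(backend, term)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table '%s': %d words x %d dims>\n",
              x$name, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Fraction of terms a backend covers
#'
#' Coverage is the share of query terms for which the backend can offer
#' at least one explanation.
#'
#' @param backend any backend supporting [lookup()].
#' @param terms character vector of query terms (non-empty).
#' @return a fraction in `[0, 1]`.
#' @export
coverage_of <- function(backend, terms) {
  mg_assert(length(terms) > 0, "`terms` must be non-empty")
  covered <- vapply(terms, function(t) nrow(lookup(backend, t)) > 0, logical(1))
  mean(covered)
}
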