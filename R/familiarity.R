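#' Background word-frequency table
#'
#' Term familiarity estimates how difficult a term is from how often it
#' occurs in general language use, approximated by a large background
#' unigram frequency list (a web-corpus-style ranking).  Terms are
#' dense-ranked by descending count (equal counts share a rank), and a
#' rank threshold -- by default the 5000th-ranked term -- defines the
#' difficulty cutoff: a term is \emph{difficult} when its background
#' frequency is strictly below the threshold term's frequency.
#'
#' When the list has fewer distinct ranks than `threshold_rank`, the
#' threshold count falls back to the smallest count present, so only
#' terms rarer than everything listed (including absent terms, counted
#' as frequency 0) are difficult.
#'
#' @param counts data frame with columns `term`, `count`, or a path to
#'   a TSV file with that header.
#' @param threshold_rank difficulty rank cutoff (default 5000).
#' @return an object of class `frequency_table`: list with `table`
#'   (term, count, rank), `threshold_rank`, `threshold_count`.
#' @export
frequency_table <- function(counts, threshold_rank = 5000L) {
  if (is.character(counts) && length(counts) == 1) {
    mg_assert(file.exists(counts), "frequency list not found: ", counts)
    counts <- read.delim(counts, sep = "\t", header = TRUE, quote = "",
                         fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  }
  mg_assert(is.data.frame(counts) && all(c("term", "count") %in% names(counts)),
            "`counts` needs columns term, count")
  mg_assert(nrow(counts) > 0, "frequency list is empty")
  mg_assert(threshold_rank >= 1, "`threshold_rank` must be >= 1")
  tab <- data.frame(term = mg_normalize(counts$term),
                    count = as.numeric(counts$count),
                    stringsAsFactors = FALSE)
  mg_assert(!anyDuplicated(tab$term), "duplicate terms in frequency list")
  mg_assert(all(tab$count >= 0), "counts must be non-negative")
  # dense rank by descending count: equal counts share a rank
  tab$rank <- match(-tab$count, sort(unique(-tab$count)))
  tab <- tab[order(tab$rank, tab$term, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  at_thresh <- tab$count[tab$rank == min(threshold_rank, max(tab$rank))][1]
  structure(list(table = tab,
                 threshold_rank = as.integer(threshold_rank),
                 threshold_count = at_thresh),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table: %d terms, threshold rank %d (count %g)>\n",
              nrow(x$table), x$threshold_rank, x$threshold_count))
  invisible(x)
}

term_frequency <- function(freq, terms) {
  i <- match(terms, freq$table$term)
  ifelse(is.na(i), 0, freq$table$count[i])
}

#' Tokenize documents into lowercase word tokens
#'
#' Tokens are maximal runs of Unicode letters, lowercased and
#' NFC-normalized.  Multiword phrases are not extracted.
#'
#' @param texts character vector of document texts.
#' @return list of character vectors, one per document.
#' @export
tokenize_documents <- function(texts) {
  toks <- stringi::stri_extract_all_regex(mg_normalize(texts), "\\p{L}+")
  lapply(toks, function(t) t[!is.na(t)])
}

#' Extract difficult terms from a document collection
#'
#' Tokenizes each document and keeps the unique terms whose background
#' frequency is strictly below the threshold term's frequency (terms
#' absent from the background list count as frequency 0 and are always
#' difficult).  A term occurring in several documents is attributed to
#' the first document containing it, in input order.
#'
#' @param documents data frame with columns `doc_id`, `doc_class`
#'   (`"encyclopedic"` or `"technical"`) and `text`.
#' @param freq a [frequency_table()].
#' @return data frame of term records: `term`, `frequency`,
#'   `source_doc`, `doc_class`.
#' @export
extract_difficult_terms <- function(documents, freq) {
  mg_assert(is.data.frame(documents) &&
              all(c("doc_id", "doc_class", "text") %in% names(documents)),
            "`documents` needs columns doc_id, doc_class, text")
  mg_assert(nrow(documents) > 0, "empty document set")
  mg_assert(inherits(freq, "frequency_table"), "`freq` is not a frequency_table")
  toks <- tokenize_documents(documents$text)
  recs <- data.frame(
    term = unlist(toks),
    source_doc = rep(documents$doc_id, lengths(toks)),
    doc_class = rep(documents$doc_class, lengths(toks)),
    stringsAsFactors = FALSE)
  recs <- recs[!duplicated(recs$term), , drop = FALSE]
  recs$frequency <- term_frequency(freq, recs$term)
  difficult <- recs$frequency < freq$threshold_count
  out <- recs[difficult, c("term", "frequency", "source_doc", "doc_class"),
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign frequency tertile groups
#'
#' Splits difficult-term records into frequency tertiles: the lowest
#' third of frequencies becomes the `low` group, the uppermost third
#' `high`, the rest `middle`.  Ties are ordered lexicographically by
#' term before slicing, so group assignment is deterministic.  When all
#' frequencies are equal no tertile structure exists: every record goes
#' to `middle` with a warning.
#'
#' @param records term records from [extract_difficult_terms()] (at
#'   least 3 rows).
#' @return `records` with an added `freq_group` column.
#' @export
assign_frequency_groups <- function(records) {
  mg_assert(is.data.frame(records) &&
              all(c("term", "frequency") %in% names(records)),
            "`records` needs columns term, frequency")
  n <- nrow(records)
  mg_assert(n >= 3, "need at least 3 records to form tertiles")
  if (length(unique(records$frequency)) == 1) {
    warning("all frequencies equal; no tertile structure (all 'middle')")
    records$freq_group <- "middle"
    return(records)
  }
  ord <- order(records$frequency, records$term, method = "radix")
  k <- n %/% 3L
  group <- rep("middle", n)
  group[ord[seq_len(k)]] <- "low"
  group[ord[seq.int(n - k + 1L, n)]] <- "high"
  records$freq_group <- group
  records
}

#' Draw a balanced stimulus sample
#'
#' Samples `n_per_class` terms from each document class, split evenly
#' between the low- and high-frequency groups, and spread across the
#' class's documents so that per-document counts differ by at most one.
#' Middle-tertile terms are never sampled.  Sampling is reproducible
#' under `seed` and never duplicates a term.
#'
#' @param records term records with `freq_group` assigned.
#' @param n_per_class even number of terms to draw per document class.
#' @param seed integer seed.
#' @return data frame of sampled term records.
#' @export
balanced_sample <- function(records, n_per_class, seed = 1L) {
  mg_assert(is.data.frame(records) &&
              all(c("term", "frequency", "source_doc", "doc_class",
                    "freq_group") %in% names(records)),
            "`records` needs freq_group (run assign_frequency_groups first)")
  mg_assert(n_per_class >= 0, "`n_per_class` must be >= 0")
  if (n_per_class == 0) return(records[0, , drop = FALSE])
  mg_assert(n_per_class %% 2 == 0,
            "`n_per_class` must be even (split across low and high groups)")

  with_seed(seed, {
    picked <- list()
    for (cls in sort(unique(records$doc_class))) {
      docs <- sort(unique(records$source_doc[records$doc_class == cls]))
      mg_assert(length(docs) > 0, "no documents in class '", cls, "'")
      pools <- list()
      for (d in docs) {
        for (g in c("low", "high")) {
          pools[[paste(d, g)]] <- which(records$doc_class == cls &
                                          records$source_doc == d &
                                          records$freq_group == g)
        }
      }
      half <- n_per_class %/% 2L
      need <- c(low = half, high = half)
      counts <- setNames(rep(0L, length(docs)), docs)
      sel <- integer()
      # greedy fill: always extend the least-loaded document that can
      # still supply a needed group, so per-document counts stay within
      # one of each other whenever a balanced assignment exists
      while (sum(need) > 0) {
        open <- names(need)[need > 0]
        elig <- vapply(docs, function(d) {
          any(lengths(pools[paste(d, open)]) > 0)
        }, logical(1))
        if (!any(elig)) {
          mg_stop("infeasible quota: class '", cls, "' still needs ",
                  need[["low"]], " low / ", need[["high"]],
                  " high term(s) but no document has eligible records left")
        }
        cand <- docs[elig]
        cand <- cand[counts[cand] == min(counts[cand])]
        d <- if (length(cand) == 1) cand else sample(cand, 1)
        gs <- open[lengths(pools[paste(d, open)]) > 0]
        g <- gs[order(-need[gs], gs)][1]   # larger remaining need first
        pool <- pools[[paste(d, g)]]
        pick <- if (length(pool) == 1) pool else sample(pool, 1)
        sel <- c(sel, pick)
        pools[[paste(d, g)]] <- setdiff(pool, pick)
        need[[g]] <- need[[g]] - 1L
        counts[[d]] <- counts[[d]] + 1L
      }
      if (max(counts) - min(counts) > 1) {
        worst <- names(counts)[which.min(counts)]
        mg_stop("infeasible quota: document '", worst, "' (class '", cls,
                "') has too few eligible terms to keep per-document ",
                "counts within 1")
      }
      picked[[cls]] <- records[sel, , drop = FALSE]
    }
    out <- do.call(rbind, picked)
    rownames(out) <- NULL
    out
  })
}
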