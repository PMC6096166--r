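#' Affix dictionaries
#'
#' A medical affix is a bound morphological unit -- a prefix or a suffix,
#' typically of Greek or Latin origin -- that carries its own denotation
#' apart from the word it occurs in (e.g. \emph{cardio-} "the heart",
#' \emph{-dipsia} "(condition of) thirst").  An affix dictionary holds,
#' for one language, the set of known affixes together with a
#' plain-language definition for each.
#'
#' Entries are kept in matching order: strictly non-increasing form
#' length, ties broken lexicographically.  Longest-first order is what
#' prevents spurious matches during parsing (\emph{anti-} must match in
#' \emph{antihero} before \emph{a-} would).
#'
#' @param entries data frame with columns `form`, `position`
#'   (`"prefix"`/`"suffix"`), `definition`, and optionally `origin` and
#'   `language`.  Forms are normalized on construction: lowercased,
#'   Unicode-NFC, leading/trailing hyphen markers stripped.
#' @param language `"en"` or `"es"`.
#' @return an object of class `affix_dictionary`: a list with elements
#'   `language` and `entries` (the normalized, ordered data frame).
#' @examples
#' d <- affix_dictionary(
#'   data.frame(form = c("anti-", "a-"), position = "prefix",
#'              definition = c("against", "not, without")),
#'   language = "en")
#' candidate_affixes(d, "prefix")$form
#' @export
affix_dictionary <- function(entries, language = c("en", "es")) {
  language <- match.arg(language)
  mg_assert(is.data.frame(entries), "`entries` must be a data frame")
  needed <- c("form", "position", "definition")
  missing_cols <- setdiff(needed, names(entries))
  mg_assert(length(missing_cols) == 0,
            "affix entries lack column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(entries$origin)) entries$origin <- NA_character_
  if (is.null(entries$language)) entries$language <- language

  bad <- which(is.na(entries$form) | !nzchar(trimws(entries$form)) |
                 is.na(entries$position) | !nzchar(trimws(entries$position)))
  if (length(bad) > 0) {
    mg_stop("affix record(s) lacking form or position at row(s): ",
            paste(bad, collapse = ", "))
  }

  form <- mg_normalize(trimws(entries$form), strip_hyphens = TRUE)
  bad <- which(!nzchar(form) | !has_only_letters(form))
  if (length(bad) > 0) {
    mg_stop("invalid affix form (empty, or containing non-letter characters ",
            "after normalization) at row(s): ", paste(bad, collapse = ", "))
  }
  position <- tolower(trimws(entries$position))
  bad <- which(!position %in% c("prefix", "suffix"))
  if (length(bad) > 0) {
    mg_stop("affix position must be 'prefix' or 'suffix' at row(s): ",
            paste(bad, collapse = ", "))
  }
  lang_tags <- tolower(trimws(as.character(entries$language)))
  bad <- which(!is.na(lang_tags) & lang_tags != language)
  if (length(bad) > 0) {
    mg_stop("language tag does not match requested language '", language,
            "' at row(s): ", paste(bad, collapse = ", "))
  }

  key <- paste(form, position)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    mg_stop("duplicate (form, position) pair(s): ", paste(dup, collapse = ", "))
  }

  out <- data.frame(form = form, position = position,
                    definition = as.character(entries$definition),
                    origin = as.character(entries$origin),
                    language = language,
                    stringsAsFactors = FALSE)
  ord <- order(-nchar(out$form), out$form, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(language = language, entries = out),
            class = "affix_dictionary")
}

#' Read an affix dictionary from a TSV file
#'
#' The file format is UTF-8 tab-separated values with header
#' `form position definition origin language`.  Forms may carry the
#' conventional hyphen markers (`adip-`, `-opsia`); they are stripped on
#' load.
#'
#' @param path path to the TSV file.
#' @param language language the dictionary is expected to be in
#'   (`"en"` or `"es"`); a record tagged with a different language is an
#'   error.
#' @return an [affix_dictionary()].
#' @export
load_affix_dictionary <- function(path, language = c("en", "es")) {
  language <- match.arg(language)
  mg_assert(file.exists(path), "affix dictionary file not found: ", path)
  mg_assert(file.size(path) > 0, "affix dictionary file is empty: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE,
                    colClasses = "character")
  mg_assert(nrow(raw) > 0, "affix dictionary has a header but no records: ", path)
  affix_dictionary(raw, language = language)
}

#' Write an affix dictionary to its TSV format
#'
#' @param dict an [affix_dictionary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_affix_dictionary <- function(dict, path) {
  mg_assert(inherits(dict, "affix_dictionary"), "not an affix_dictionary")
  write.table(dict$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Enumerate candidate affixes of one position class
#'
#' Returns the dictionary's prefixes or suffixes in matching order:
#' longest form first, equal lengths broken lexicographically.  The
#' parser tries candidates in exactly this order.
#'
#' @param dict an [affix_dictionary()].
#' @param position `"prefix"` or `"suffix"`.
#' @return data frame of affix entries (possibly zero rows), ordered
#'   longest-first.
#' @export
candidate_affixes <- function(dict, position = c("prefix", "suffix")) {
  position <- match.arg(position)
  mg_assert(inherits(dict, "affix_dictionary"), "not an affix_dictionary")
  out <- dict$entries[dict$entries$position == position, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.affix_dictionary <- function(x, ...) {
  cat(sprintf("<affix_dictionary [%s]: %d prefixes, %d suffixes>\n",
              x$language,
              sum(x$entries$position == "prefix"),
              sum(x$entries$position == "suffix")))
  invisible(x)
}

#' @export
format.affix_dictionary <- function(x, ...) {
  sprintf("<affix_dictionary [%s], %d entries>", x$language, nrow(x$entries))
}
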